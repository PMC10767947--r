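## Condition helpers: every user-facing failure carries a class so the CLI can
## translate validation failures vs usage mistakes into distinct exit codes.

abort_parse <- function(msg) abort(msg, class = c("pathmosaic_parse_error", "pathmosaic_error"))
abort_validation <- function(msg) abort(msg, class = c("pathmosaic_validation_error", "pathmosaic_error"))
abort_config <- function(msg) abort(msg, class = c("pathmosaic_config_error", "pathmosaic_error"))
abort_domain <- function(msg) abort(msg, class = c("pathmosaic_domain_error", "pathmosaic_error"))
abort_lookup <- function(msg) abort(msg, class = c("pathmosaic_lookup_error", "pathmosaic_error"))
abort_contract <- function(msg) abort(msg, class = c("pathmosaic_contract_error", "pathmosaic_error"))
abort_usage <- function(msg) abort(msg, class = c("pathmosaic_usage_error", "pathmosaic_error"))

split_bar <- function(x) {
  out <- strsplit(ifelse(is.na(x), "", x), "|", fixed = TRUE)
  lapply(out, function(v) v[nzchar(v)])
}

join_bar <- function(x) vapply(x, paste, character(1), collapse = "|")

## Fixed numeric formatting (6 significant digits) so TSV outputs are diffable
format_num <- function(x) {
  out <- vapply(x, function(v) {
    if (is.na(v)) return(NA_character_)
    formatC(signif(v, 6), format = "g", digits = 6)
  }, character(1))
  out
}

is_count <- function(x) {
  is.numeric(x) && all(!is.na(x)) && all(x >= 0) && all(x == floor(x))
}
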