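#' Derive a child seed from a master seed
#'
#' Every stochastic operation in the package derives its own RNG seed from
#' the master seed, an operation label and an optional index, so that
#' per-family and per-stage draws are reproducible independently of the
#' order in which stages run.  The hash stays below 2^31 - 1.
#'
#' @param master integer master seed.
#' @param op character operation label.
#' @param index optional integer (e.g. family index).
#' @return an integer seed.
#' @export
derive_seed <- function(master, op, index = 0L) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(op))
  h <- abs(as.numeric(master)) %% 2147483647
  for (ch in utf8ToInt(op)) h <- (h * 31 + ch) %% 2147483647
  h <- (h * 31 + abs(as.numeric(index))) %% 2147483647
  as.integer(h)
}

#' Phred score of a posterior call
#'
#' \code{phred_from_posterior} maps the maximum genotype posterior p to
#' -10 log10(1 - p); \code{is_low_quality} applies the strict Q20 rule:
#' a call is flagged iff its phred score is strictly below 20, so a call
#' with posterior exactly 0.99 (phred 20) is \emph{not} flagged.
#'
#' @param posterior maximum genotype posterior probability in [0, 1].
#' @return phred-scaled quality (capped at 990 to avoid infinities).
#' @export
phred_from_posterior <- function(posterior) {
  stopifnot(all(posterior >= 0 & posterior <= 1))
  pmin(-10 * log10(pmax(1 - posterior, 1e-99)), 990)
}

#' @rdname phred_from_posterior
#' @param phred phred-scaled posterior quality.
#' @param threshold flagging threshold (default Q20).
#' @export
is_low_quality <- function(phred, threshold = 20) {
  # strict "< Q20" up to floating-point noise: a posterior of exactly 0.99
  # maps to phred 20 - 4e-15 and must not be flagged
  (threshold - phred) > 1e-9
}

# FNV-1a style hash of a deparsed object, for provenance headers.
config_hash <- function(x) {
  txt <- paste(deparse(x), collapse = "")
  h <- 2166136261
  for (ch in utf8ToInt(txt)) {
    h <- bitwXor(as.integer(h %% 2147483647), ch)
    h <- (h * 16777619) %% 2147483647
  }
  sprintf("%08x", as.integer(h))
}

# Write a data.frame as TSV with '#key=value' provenance header lines.
write_tsv_provenance <- function(df, path, seed = NA, extra = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("#tool=triorare %s", as.character(packageVersion("triorare"))), con)
  if (!is.na(seed)) writeLines(sprintf("#seed=%s", format(seed)), con)
  for (e in extra) writeLines(paste0("#", e), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Read a TSV written by write_tsv_provenance (skips '#' header lines).
read_tsv_provenance <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
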