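# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop2 <- function(...) stop(..., call. = FALSE)

#' Derive a stage-specific seed from a global seed
#'
#' Fans a single global seed out to per-stage seeds by hashing the stage name,
#' so each pipeline stage is independently reproducible. The result always
#' fits in a 32-bit integer.
#'
#' @param seed Integer global seed.
#' @param stage Character stage name.
#' @return An integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((abs(seed) + 1000003 * h) %% .Machine$integer.max)
}

# check a numeric matrix has unique dimnames and finite values
check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || !is.numeric(x)) stop2(what, " must be a numeric matrix")
  if (is.null(rownames(x)) || is.null(colnames(x)))
    stop2(what, " must have row and column names")
  if (anyDuplicated(rownames(x))) stop2(what, ": duplicate row ids")
  if (anyDuplicated(colnames(x))) stop2(what, ": duplicate column ids")
  if (!all(is.finite(x))) stop2(what, ": non-finite values")
  invisible(x)
}

check_design <- function(design) {
  need <- c("sample_id", "treatment", "timepoint", "replicate")
  if (!is.data.frame(design) || !all(need %in% names(design)))
    stop2("design must be a data.frame with columns ",
          paste(need, collapse = ", "))
  if (anyDuplicated(design$sample_id)) stop2("design: duplicate sample_ids")
  invisible(design)
}
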