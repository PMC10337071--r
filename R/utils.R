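#' Derive a reproducible stage seed from a master seed
#'
#' Every stochastic stage of the pipeline draws its own seed
#' deterministically from one master seed and a stage label, so that stages
#' can be re-run in isolation without replaying the whole pipeline RNG
#' stream.
#'
#' @param master Integer master seed.
#' @param stage Character stage label (e.g. `"simulate"`, `"ensemble"`).
#' @return An integer seed in `[0, 2^31 - 1)`.
#' @export
#' @examples
#' derive_seed(1, "ensemble")
derive_seed <- function(master, stage) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(stage))
  h <- sum(as.integer(utf8ToInt(stage)) * seq_along(utf8ToInt(stage)) * 131)
  as.integer((abs(master) * 48271 + h) %% (2^31 - 1))
}

# abundance tibble (sample_id + numeric ASV columns) -> counts matrix with
# rownames = sample ids
abund_matrix <- function(abund) {
  stopifnot(is.data.frame(abund), "sample_id" %in% names(abund))
  m <- as.matrix(abund[setdiff(names(abund), "sample_id")])
  if (!is.numeric(m)) abort("abundance columns must be numeric")
  rownames(m) <- as.character(abund$sample_id)
  m
}

matrix_abund <- function(m) {
  dplyr::bind_cols(tibble(sample_id = rownames(m)), as_tibble(m))
}

# numeric-columns-only matrix from a metadata tibble
meta_matrix <- function(tbl, id = "sample_id") {
  m <- as.matrix(tbl[setdiff(names(tbl), id)])
  rownames(m) <- as.character(tbl[[id]])
  m
}

check_sample_alignment <- function(...) {
  ids <- lapply(list(...), function(x) as.character(x$sample_id))
  if (!all(vapply(ids[-1], identical, logical(1), ids[[1]]))) {
    abort("inputs are not sample-aligned (sample_id columns differ)")
  }
  invisible(TRUE)
}
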