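#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement between two labelings of the same items
#' (Hubert-Arabie adjustment); 1 means identical partitions, 0 is the
#' expectation under random labeling.
#'
#' @param a,b Label vectors of equal length.
#' @return Numeric scalar in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  tab <- table(a, b)
  n <- length(a)
  ch2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(ch2(tab))
  sum_a <- sum(ch2(rowSums(tab)))
  sum_b <- sum(ch2(colSums(tab)))
  expected <- sum_a * sum_b / ch2(n)
  max_idx <- (sum_a + sum_b) / 2
  if (abs(max_idx - expected) < .Machine$double.eps) return(1)
  (sum_ij - expected) / (max_idx - expected)
}

pkg_log <- function(stage, ..., verbose = TRUE) {
  if (verbose) {
    message(sprintf("[%s] %s %s", format(Sys.time(), "%H:%M:%S"),
                    stage, paste0(..., collapse = "")))
  }
  invisible(NULL)
}
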