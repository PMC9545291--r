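#' Generate a pseudo-random oddball stimulus sequence
#'
#' Produces an ordered sequence over \{S, D1, D2\} with the study's
#' constraints: the sequence starts with at least one standard and no two
#' deviants are adjacent (every deviant is immediately preceded by a
#' standard). Deviants are placed by sampling, without replacement,
#' distinct "slots" following each standard, which enforces both
#' constraints by construction.
#'
#' @param n_s,n_d1,n_d2 counts of standards, increasing deviants and
#'   decreasing deviants (defaults 800/100/100).
#' @param paradigm `"frequency"` or `"intensity"` (label only).
#' @param seed integer seed; the sequence is reproducible given the seed.
#' @return an object of class `oddball_sequence`: a character vector of
#'   labels with attributes `paradigm` and `counts`.
#' @examples
#' s <- generate_oddball_sequence(seed = 1)
#' table(s)
#' @export
generate_oddball_sequence <- function(n_s = 800, n_d1 = 100, n_d2 = 100,
                                      paradigm = c("frequency", "intensity"),
                                      seed = 1) {
  paradigm <- match.arg(paradigm)
  n_d <- n_d1 + n_d2
  if (n_s < n_d)
    stop("infeasible counts: need at least one standard per deviant")
  labels <- with_seed(seed, {
    slots <- sort(sample.int(n_s, n_d))      # deviant goes right after standard `slot`
    dev_lab <- sample(c(rep("D1", n_d1), rep("D2", n_d2)))
    out <- character(n_s + n_d)
    pos <- 1L
    di <- 1L
    for (k in seq_len(n_s)) {
      out[pos] <- "S"
      pos <- pos + 1L
      if (di <= n_d && slots[di] == k) {
        out[pos] <- dev_lab[di]
        pos <- pos + 1L
        di <- di + 1L
      }
    }
    out
  })
  structure(labels, paradigm = paradigm,
            counts = c(S = n_s, D1 = n_d1, D2 = n_d2),
            class = "oddball_sequence")
}

#' @export
print.oddball_sequence <- function(x, ...) {
  cn <- attr(x, "counts")
  cat(sprintf("<oddball_sequence> %s paradigm, %d stimuli (%d S, %d D1, %d D2)\n",
              attr(x, "paradigm"), length(x), cn["S"], cn["D1"], cn["D2"]))
  invisible(x)
}

#' Indices of standards immediately preceding a deviant
#'
#' @param sequence an `oddball_sequence` (or plain label vector).
#' @return integer positions of the retained standard trials.
#' @export
standards_before_deviants <- function(sequence) {
  lab <- as.character(sequence)
  n <- length(lab)
  which(lab == "S" & c(lab[-1], "S") != "S")
}
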