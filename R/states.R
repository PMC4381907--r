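#' Enumerate the aggregated channel states
#'
#' The channel is modelled as one pore (closed `C` or open `O`) coupled to
#' `n_vsd` identical, non-cooperative voltage-sensing domains (VSDs), each of
#' which occupies a resting (`R`), intermediate (`I`) or activated (`A`)
#' conformation.  Because the VSDs are interchangeable, a channel state is
#' fully described by the pore state plus the *counts* of VSDs in each
#' conformation.  For the physiological tetramer this gives 15 VSD-count
#' combinations and 30 channel states in total.
#'
#' The canonical ordering is: all closed states first, then all open states;
#' within each pore block, states are sorted lexicographically *descending*
#' on `(n_R, n_I, n_A)`, so the first state is `C_RRRR` and the last is
#' `O_AAAA`.  All rate matrices and occupancy vectors in the package index
#' states in this order.
#'
#' @param n_vsd number of voltage-sensing domains (default 4).
#' @return A data frame with one row per state and columns `pore` (factor
#'   `"C"`/`"O"`), `n_R`, `n_I`, `n_A` (integer counts summing to `n_vsd`),
#'   and `label` (e.g. `"C_RRIA"`).
#' @examples
#' st <- enumerate_states()
#' nrow(st)        # 30
#' head(st$label)
#' @export
enumerate_states <- function(n_vsd = 4L) {
  n_vsd <- as.integer(n_vsd)
  stopifnot(n_vsd >= 1L)
  combos <- list()
  for (n_R in n_vsd:0) {
    for (n_I in (n_vsd - n_R):0) {
      n_A <- n_vsd - n_R - n_I
      combos[[length(combos) + 1L]] <- c(n_R, n_I, n_A)
    }
  }
  cc <- do.call(rbind, combos)
  st <- data.frame(
    pore = rep(c("C", "O"), each = nrow(cc)),
    n_R  = rep(cc[, 1], 2L),
    n_I  = rep(cc[, 2], 2L),
    n_A  = rep(cc[, 3], 2L),
    stringsAsFactors = FALSE
  )
  st$label <- state_labels(st)
  st
}

#' Canonical state labels
#'
#' Builds labels in the `C_RRRR` style: the pore letter followed by one
#' letter per VSD, resting first (`C_RRIA` is closed with two resting, one
#' intermediate and one activated VSD).
#'
#' @param states a data frame as returned by [enumerate_states()].
#' @return character vector of labels.
#' @export
state_labels <- function(states) {
  vapply(seq_len(nrow(states)), function(i) {
    paste0(states$pore[i], "_",
           strrep("R", states$n_R[i]),
           strrep("I", states$n_I[i]),
           strrep("A", states$n_A[i]))
  }, character(1))
}

## index of a (pore, n_R, n_I, n_A) combination in the canonical order
state_index <- function(states, pore, n_R, n_I, n_A) {
  which(states$pore == pore & states$n_R == n_R &
          states$n_I == n_I & states$n_A == n_A)
}
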