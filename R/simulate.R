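# Simulation benchmark: rearrange a reference, fragment it into contigs,
# re-order the contigs with the solver, and score the normalized contig
# mis-join error.  All randomness comes from R's global RNG; the
# benchmark driver seeds it and derives per-repetition sub-seeds.

#' Apply random reversals/transpositions to the identity gene order
#'
#' Starts from `(1, ..., n)` and applies `delta` random events; each
#' event is a reversal with probability `r/(r+t)` (ratio `c(r, t)`) and
#' a transposition otherwise.  Reversal endpoints are a uniform ordered
#' position pair; a transposition exchanges the two adjacent segments cut
#' by three uniform distinct cut points.
#'
#' @param n Gene count.
#' @param delta Number of rearrangement events.
#' @param ratio Length-2 numeric: relative occurrence of reversals and
#'   transpositions, e.g. `c(2, 1)`.
#' @return Signed integer sequence of length `n`.
#' @export
random_rearranged_genome <- function(n, delta, ratio = c(1, 1)) {
  stopifnot(n >= 1L, delta >= 0L, length(ratio) == 2L, sum(ratio) > 0)
  s <- seq_len(n)
  p_rev <- ratio[1] / sum(ratio)
  for (k in seq_len(delta)) {
    if (stats::runif(1) < p_rev) {
      ij <- sort(sample.int(n, 2L, replace = TRUE))
      s[ij[1]:ij[2]] <- -rev(s[ij[1]:ij[2]])
    } else {
      if (n < 2L) next  # no transposition exists on a single gene
      cuts <- sort(sample(0:n, 3L))
      p <- cuts[1]; q <- cuts[2]; r <- cuts[3]
      s <- c(s[seqi(1L, p)], s[seqi(q + 1L, r)], s[seqi(p + 1L, q)], s[seqi(r + 1L, n)])
    }
  }
  as.integer(s)
}

#' Fragment a signed sequence into a draft genome
#'
#' Draws `m - 1` distinct cut positions uniformly from the `n - 1`
#' internal adjacencies, reverse-complements each resulting contig
#' independently with probability 1/2, and shuffles the contig order
#' (draft genomes are unordered sets).
#'
#' @param perm Signed integer sequence.
#' @param m Number of contigs, `1 <= m <= n`.
#' @return A `draft_genome`.
#' @export
fragment_genome <- function(perm, m) {
  n <- length(perm)
  if (m < 1L || m > n) stop("need 1 <= m <= n")
  cuts <- if (m > 1L) sort(sample.int(n - 1L, m - 1L)) else integer(0)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts, n)
  blocks <- lapply(seq_len(m), function(i) {
    b <- perm[starts[i]:ends[i]]
    if (stats::runif(1) < 0.5) -rev(b) else b
  })
  ord <- sample.int(m)
  draft_genome(blocks[ord], n = n, names = paste0("C", ord))
}

#' Contig mis-join error of a predicted assembly
#'
#' Counts the breakpoints of the predicted signed sequence against the
#' true one: an adjacency `(a, b)` of the prediction is correct iff the
#' truth contains `(a, b)` or its reverse complement `(-b, -a)`.  When
#' the contigs were cut from the truth, every breakpoint sits at one of
#' the `m - 1` contig junctions, so the count is a mis-join count; the
#' better of the prediction and its full reverse complement is taken,
#' and the count is normalized by `m - rho`.
#'
#' @param predicted,truth Signed sequences over the same gene set.
#' @param m Contig count of the draft the prediction came from.
#' @param rho 1 for a linear chromosome (no error possible at the ends),
#'   0 for circular.
#' @return A list with `count` and `normalized`.
#' @export
misjoin_error <- function(predicted, truth, m, rho = 1L) {
  if (!setequal(abs(predicted), abs(truth)) ||
      length(predicted) != length(truth)) {
    stop("predicted and truth are not over the same gene set")
  }
  adj_keys <- function(s) {
    if (length(s) < 2L) return(character(0))
    a <- s[-length(s)]; b <- s[-1L]
    paste(a, b)
  }
  truth_set <- c(adj_keys(truth), adj_keys(-rev(truth)))
  count_of <- function(s) sum(!(adj_keys(s) %in% truth_set))
  count <- min(count_of(predicted), count_of(-rev(predicted)))
  denom <- m - rho
  normalized <- if (denom > 0L) count / denom else 0
  list(count = as.integer(count), normalized = normalized)
}

parse_ratio <- function(ratio) {
  if (is.character(ratio)) {
    parts <- as.numeric(strsplit(ratio, ":", fixed = TRUE)[[1]])
    if (length(parts) != 2L || anyNA(parts)) stop("malformed ratio: ", ratio)
    return(parts)
  }
  as.numeric(ratio)
}

#' Run the contig-ordering simulation benchmark
#'
#' For every combination of `delta` and `ratio`: rearrange the identity
#' reference with `delta` random events, fragment into `m` contigs,
#' re-order the contigs with [block_order()], and score the normalized
#' mis-join error against the true sequence, `reps` times.  Fully seeded
#' and reproducible: per-repetition sub-seeds are drawn up front from the
#' given seed.
#'
#' @param n Gene count.
#' @param m Contig count.
#' @param deltas Integer vector of event counts.
#' @param ratios List (or character vector like `"2:1"`) of
#'   reversal:transposition occurrence ratios.
#' @param reps Repetitions per cell.
#' @param seed Integer RNG seed.
#' @param rho 1 for linear chromosomes.
#' @return A data frame with one row per repetition: `n`, `m`, `delta`,
#'   `ratio`, `rep`, `seed`, `misjoins`, `normalized_error`, `distance`.
#' @export
run_benchmark <- function(n, m, deltas, ratios = c("1:0", "2:1", "1:1", "0:1"),
                          reps = 10L, seed = 1L, rho = 1L) {
  stopifnot(reps >= 1L, all(deltas >= 0L), m >= 1L, m <= n)
  if (!is.list(ratios)) ratios <- as.list(ratios)
  set.seed(seed)
  cells <- expand.grid(delta = deltas, ratio_i = seq_along(ratios), rep = seq_len(reps))
  subseeds <- sample.int(.Machine$integer.max, nrow(cells))
  rows <- vector("list", nrow(cells))
  for (k in seq_len(nrow(cells))) {
    delta <- cells$delta[k]
    ratio <- parse_ratio(ratios[[cells$ratio_i[k]]])
    set.seed(subseeds[k])
    truth <- random_rearranged_genome(n, delta, ratio)
    draft <- fragment_genome(truth, m)
    fit <- block_order(draft, reference_genome(seq_len(n)))
    err <- misjoin_error(fit$assembly, truth, m, rho)
    rows[[k]] <- data.frame(
      n = n, m = m, delta = delta,
      ratio = paste(ratios[[cells$ratio_i[k]]], collapse = ":"),
      rep = cells$rep[k], seed = subseeds[k],
      misjoins = err$count, normalized_error = err$normalized,
      distance = fit$distance, stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  out[order(out$ratio, out$delta, out$rep), , drop = FALSE]
}

#' Write a benchmark table as TSV
#' @param table Data frame from [run_benchmark()].
#' @param path Output file path.
#' @return Invisibly, `path`.
#' @export
write_benchmark <- function(table, path) {
  utils::write.table(table, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
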