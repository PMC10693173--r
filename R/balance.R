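# ADASYN adaptive oversampling.
#
# Synthetic minority samples are allocated in proportion to each minority
# point's local density weight and generated by random interpolation toward
# same-class nearest neighbours.  Two sizing modes are provided:
# "standard" generates G = n_majority - n_minority synthetics (balancing the
# classes), while "paper" generates IR * n_minority = n_majority synthetics
# the literal ratio-sized formulation (which overshoots: the minority ends up larger
# than the majority; retained as a fidelity switch).

.euclid <- function(a, b) sqrt(rowSums((a - matrix(b, nrow(a), length(b), byrow = TRUE))^2))

#' Plan ADASYN oversampling for one minority class
#'
#' Computes the imbalance ratio IR = n_majority / n_minority, the total
#' synthetic count for the requested mode, and per-minority-sample
#' quantities: the mean Euclidean distance to the k nearest neighbours in
#' the full feature space, the relative contribution
#' `rc(x_i) = dist(x_i) / sum(dist)`, the density distribution
#' `dd(x_i) = rc(x_i) / sum(rc)`, and the synthetic count
#' `N_i = dd(x_i) * N_total` apportioned by largest remainder.
#'
#' @param features Numeric matrix or data frame.
#' @param labels Class label vector, same length as rows of `features`.
#' @param minority Class id to oversample.
#' @param k Neighbour count (default 5), truncated with a warning when it
#'   exceeds the available neighbours.
#' @param mode `"standard"` (balance to the majority count) or `"paper"`
#'   (the literal `IR * n_minority` total).
#' @return An object of class `adasyn_plan`.
#' @export
adasyn_plan <- function(features, labels, minority, k = 5,
                        mode = c("standard", "paper")) {
  mode <- match.arg(mode)
  x <- as.matrix(features)
  stopifnot(nrow(x) == length(labels), k >= 1)
  counts <- table(labels)
  if (!as.character(minority) %in% names(counts)) stop("unknown minority class")
  n_min <- as.integer(counts[[as.character(minority)]])
  n_maj <- as.integer(max(counts))
  if (n_min < 2) stop("minority class needs at least 2 samples")
  ir <- n_maj / n_min
  n_total <- if (mode == "paper") round(ir * n_min) else max(0L, n_maj - n_min)
  idx_min <- which(labels == minority)
  kk <- min(k, nrow(x) - 1L)
  if (kk < k) warning("k truncated to ", kk, " (not enough rows)")
  dist_i <- vapply(idx_min, function(i) {
    d <- .euclid(x[-i, , drop = FALSE], x[i, ])
    mean(sort(d)[seq_len(kk)])
  }, numeric(1))
  rc <- if (sum(dist_i) > 0) dist_i / sum(dist_i) else rep(1 / n_min, n_min)
  dd <- rc / sum(rc)
  n_i <- largest_remainder(dd, n_total)
  structure(list(imbalance_ratio = ir, n_synthetic_total = as.integer(n_total),
                 minority = minority, k = kk, mode = mode,
                 per_sample = data.frame(index = idx_min, dist = dist_i,
                                         rc = rc, dd = dd, n_synthetic = n_i)),
            class = "adasyn_plan")
}

#' @export
print.adasyn_plan <- function(x, ...) {
  cat(sprintf("<adasyn_plan> class %s: IR=%.3f, %d synthetics (%s mode, k=%d)\n",
              x$minority, x$imbalance_ratio, x$n_synthetic_total, x$mode, x$k))
  invisible(x)
}

#' ADASYN resampling across all minority classes
#'
#' Every class smaller than the largest class is oversampled one-vs-largest
#' according to its [adasyn_plan()].  Each synthetic point is
#' `x_i + lambda * (x_nn - x_i)` with `lambda ~ U(0, 1)` and `x_nn` one of
#' the k nearest same-class neighbours of `x_i`, so synthetics lie on
#' segments between minority points.  The output is the original rows plus
#' the synthetics.
#'
#' @inheritParams adasyn_plan
#' @param seed RNG seed for neighbour choice and interpolation.
#' @return List with `features` (matrix), `labels`, and `synthetic` (logical
#'   marker per row).
#' @export
adasyn_resample <- function(features, labels, k = 5,
                            mode = c("standard", "paper"), seed = 1L) {
  mode <- match.arg(mode)
  x <- as.matrix(features)
  counts <- table(labels)
  largest <- names(counts)[which.max(counts)]
  local_seed(seed, {
    new_x <- list(); new_y <- list()
    for (cls in names(counts)) {
      if (cls == largest || counts[[cls]] >= max(counts)) next
      plan <- adasyn_plan(x, labels, cls, k = k, mode = mode)
      if (plan$n_synthetic_total == 0) next
      idx_min <- plan$per_sample$index
      xm <- x[idx_min, , drop = FALSE]
      kk <- min(k, nrow(xm) - 1L)
      if (kk < 1) next
      for (j in seq_len(nrow(plan$per_sample))) {
        ni <- plan$per_sample$n_synthetic[j]
        if (ni == 0) next
        xi <- xm[j, ]
        d <- .euclid(xm[-j, , drop = FALSE], xi)
        nn <- xm[-j, , drop = FALSE][order(d)[seq_len(kk)], , drop = FALSE]
        pick <- sample.int(kk, ni, replace = TRUE)
        lam <- stats::runif(ni)
        syn <- matrix(xi, ni, ncol(x), byrow = TRUE) +
          lam * (nn[pick, , drop = FALSE] - matrix(xi, ni, ncol(x), byrow = TRUE))
        new_x[[length(new_x) + 1L]] <- syn
        new_y[[length(new_y) + 1L]] <- rep(cls, ni)
      }
    }
    syn_x <- if (length(new_x)) do.call(rbind, new_x) else x[0, , drop = FALSE]
    out_x <- rbind(x, syn_x)
    rownames(out_x) <- NULL
    out_y <- c(as.character(labels), unlist(new_y) %||% character(0))
    if (is.numeric(labels)) out_y <- as.numeric(out_y)
    list(features = out_x, labels = out_y,
         synthetic = c(rep(FALSE, nrow(x)), rep(TRUE, nrow(syn_x))))
  })
}
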