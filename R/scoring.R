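#' Metric distribution over the scoring population
#'
#' Holds the multiset of values of one metric across the full cut-node
#' population (all components pooled), either as raw values or as a
#' value / occurrences histogram. Percentile scores are computed against this
#' population.
#'
#' @param values numeric vector of raw metric values (one per cut node), or
#' @param histogram data frame with columns `value` and `occurrences`
#' @param name optional metric name, carried into error messages
#' @param population_size optional explicit population size. Needed when
#'   `histogram` is a lower prefix of the full distribution (a printed
#'   excerpt): strictly-less scores of the listed values stay exact as long
#'   as every value below them is listed, but the divisor must be the full
#'   population.
#' @return a `metric_distribution`
#' @export
metric_distribution <- function(values = NULL, histogram = NULL, name = NULL,
                                population_size = NULL) {
  if (is.null(values) == is.null(histogram)) {
    stop("supply exactly one of `values` or `histogram`")
  }
  if (!is.null(values)) {
    values <- values[!is.na(values)]
    if (length(values) == 0) stop("undefined percentile population: no values",
                                  if (!is.null(name)) paste0(" for ", name))
    tb <- table(values)
    histogram <- data.frame(value = as.numeric(names(tb)),
                            occurrences = as.integer(tb))
  } else {
    stopifnot(all(c("value", "occurrences") %in% names(histogram)))
    histogram <- data.frame(value = as.numeric(histogram$value),
                            occurrences = as.integer(histogram$occurrences))
    if (nrow(histogram) == 0 || sum(histogram$occurrences) == 0) {
      stop("undefined percentile population: empty histogram",
           if (!is.null(name)) paste0(" for ", name))
    }
    if (anyDuplicated(histogram$value)) stop("duplicate histogram values")
  }
  histogram <- histogram[order(histogram$value), , drop = FALSE]
  rownames(histogram) <- NULL
  size <- if (is.null(population_size)) {
    sum(histogram$occurrences)
  } else {
    as.integer(population_size)
  }
  if (size < sum(histogram$occurrences)) {
    stop("population_size smaller than the histogram total")
  }
  structure(list(name = name, histogram = histogram, size = size),
            class = "metric_distribution")
}

#' @export
print.metric_distribution <- function(x, ...) {
  cat(sprintf("<metric_distribution>%s %d values, %d distinct\n",
              if (is.null(x$name)) "" else paste0(" ", x$name, ":"),
              x$size, nrow(x$histogram)))
  invisible(x)
}

#' Strictly-less percentile score
#'
#' The percentile score of a measure is the percentage of population values
#' that are *strictly less* than it: `100 * #(values < x) / population size`.
#' The minimum of the population scores exactly 0 (so it contributes nothing
#' to a combined score) and no value can reach 100; equal raw values always
#' receive equal scores. This brings metrics on incomparable scales (component
#' counts, patch sizes, metres) to a common 0–100 scale before summation.
#'
#' @param dist a [metric_distribution()]
#' @param x a measure value (vectorized)
#' @return numeric percentile score(s) in \[0, 100)
#' @examples
#' d <- metric_distribution(values = c(1, 1, 1, 2, 3))
#' percentile_score(d, c(1, 2, 3))
#' @export
percentile_score <- function(dist, x) {
  stopifnot(inherits(dist, "metric_distribution"))
  h <- dist$histogram
  vapply(as.numeric(x), function(xi) {
    100 * sum(h$occurrences[h$value < xi]) / dist$size
  }, numeric(1))
}

#' Combined percentile score
#'
#' Sums the (unrounded) percentile scores of the configured metrics. With `m`
#' metrics the combined score lies in \[0, 100 m); display rounding belongs to
#' report time only, so that a printed combined score is the rounding of the
#' exact sum rather than the sum of rounded addends.
#'
#' @param percentiles data frame (or named list) of percentile score columns
#' @param metric_set character vector naming the columns to sum
#' @return numeric combined scores
#' @export
combined_score <- function(percentiles, metric_set) {
  missing <- setdiff(metric_set, names(percentiles))
  if (length(missing) > 0) {
    stop("no percentile scores for metric(s): ",
         paste(missing, collapse = ", "))
  }
  Reduce(`+`, lapply(metric_set, function(m) as.numeric(percentiles[[m]])))
}

#' Rank cut nodes by combined score
#'
#' Orders records by descending combined score. Ties share the better
#' (smaller) 1-based rank position; within a tie the record with the higher
#' normalized betweenness comes first, then the smaller node id, so the
#' priority list is a total order.
#'
#' @param records data frame with at least `node_id` and `combined`; a
#'   `betweenness` column is used as first tie-break when present
#' @return the data frame reordered, with a `rank` column added
#' @export
rank_cut_nodes <- function(records) {
  stopifnot(all(c("node_id", "combined") %in% names(records)))
  btw <- if ("betweenness" %in% names(records)) records$betweenness else
    rep(0, nrow(records))
  ord <- order(-records$combined, -btw, records$node_id)
  out <- records[ord, , drop = FALSE]
  # competition ranking: 1 + number of strictly better combined scores
  out$rank <- vapply(out$combined,
                     function(s) 1L + sum(records$combined > s), integer(1))
  rownames(out) <- NULL
  out
}

#' Correlation between combined score and betweenness
#'
#' Reports the Pearson product-moment and Spearman rank correlations between
#' the combined score and the normalized betweenness over the same cut-node
#' set, the comparison used to show that the composite ranking is not simply
#' betweenness in disguise. Spearman uses mid-ranks for ties.
#'
#' @param x,y paired numeric vectors (length >= 3)
#' @return list with `pearson`, `spearman`, `n`, and `defined` (FALSE when a
#'   variable has zero variance, in which case both coefficients are `NA`)
#' @export
correlation_report <- function(x, y) {
  x <- as.numeric(x)
  y <- as.numeric(y)
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired values")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    return(list(pearson = NA_real_, spearman = NA_real_, n = length(x),
                defined = FALSE))
  }
  list(pearson = stats::cor(x, y, method = "pearson"),
       spearman = stats::cor(x, y, method = "spearman"),
       n = length(x), defined = TRUE)
}

#' Build the full ranking table
#'
#' Assembles, for every cut node, the raw metric values, their strictly-less
#' percentile scores over the pooled cut-node population, the combined score,
#' and the rank — mirroring the per-component report produced for land
#' managers. Betweenness is kept as a comparison column (with its own rank)
#' and is not part of the default combined score.
#'
#' @param metrics output of [removal_metrics()]
#' @param distances optional named numeric vector: minimum site distance per
#'   node id. Required when `"site_distance"` is in `metric_set`.
#' @param betweenness optional output of [betweenness_table()]; used for the
#'   comparison column and rank tie-breaks
#' @param metric_set metrics whose percentiles are summed; any subset of
#'   `"additional_count"`, `"second_size"`, `"site_distance"`,
#'   `"betweenness"`. Default: the three-metric score
#'   (`C_A`, `C_S`, site distance).
#' @param drop_noise drop cut nodes with `second_size == 1` (likely enclave
#'   artifacts) before scoring? Default `FALSE`.
#' @return data frame with raw values, `<metric>_pctl` columns, `combined`,
#'   `betweenness`, `betweenness_rank`, `rank`; ordered by rank
#' @export
build_ranking <- function(metrics, distances = NULL, betweenness = NULL,
                          metric_set = c("additional_count", "second_size",
                                         "site_distance"),
                          drop_noise = FALSE) {
  allowed <- c("additional_count", "second_size", "site_distance",
               "betweenness")
  bad <- setdiff(metric_set, allowed)
  if (length(bad) > 0) stop("unknown metric(s): ", paste(bad, collapse = ", "))
  if (nrow(metrics) == 0) {
    out <- metrics
    out$combined <- numeric(0)
    out$rank <- integer(0)
    return(out)
  }
  tab <- metrics
  if (drop_noise) tab <- tab[tab$second_size != 1, , drop = FALSE]
  if (nrow(tab) == 0) stop("no cut nodes left after noise filter")

  if ("site_distance" %in% metric_set) {
    if (is.null(distances)) {
      stop("metric set includes site_distance but no distances were supplied")
    }
    miss <- setdiff(tab$node_id, names(distances))
    if (length(miss) > 0) {
      stop("no site distance for node(s): ", paste(miss, collapse = ", "))
    }
    tab$site_distance <- as.numeric(distances[tab$node_id])
  }
  if (!is.null(betweenness)) {
    idx <- match(tab$node_id, betweenness$node_id)
    tab$betweenness <- betweenness$normalized[idx]
  } else if ("betweenness" %in% metric_set) {
    stop("metric set includes betweenness but no betweenness table was supplied")
  }

  for (m in metric_set) {
    dist <- metric_distribution(values = tab[[m]], name = m)
    tab[[paste0(m, "_pctl")]] <- percentile_score(dist, tab[[m]])
  }
  tab$combined <- combined_score(tab, paste0(metric_set, "_pctl"))
  if (!is.null(betweenness) && nrow(tab) > 0) {
    bord <- order(-tab$betweenness, tab$node_id)
    tab$betweenness_rank <- integer(nrow(tab))
    tab$betweenness_rank[bord] <- seq_len(nrow(tab))
  }
  rank_cut_nodes(tab)
}
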