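#' Connectance of a bipartite network
#'
#' The fraction of all possible links that are realised, `C = L / S^2`,
#' where `L` is the number of distinct links and `S` the number of species
#' present in the network (hosts plus visitors with at least one
#' interaction).
#'
#' @param net An [build_network()] object with at least one edge.
#' @return Real in `(0, 1]`.
#' @examples
#' m <- matrix(1, 2, 3)
#' connectance(network_from_matrix(m)) # 6 / 25
#' @export
connectance <- function(net) {
  L <- nrow(net$edges)
  if (L == 0) stop("connectance is undefined for an empty network",
                   call. = FALSE)
  S <- length(net$host_ids) + length(net$visitor_ids)
  L / S^2
}

# sum of paired nestedness terms along one axis (rows of b), plus pair count
nodf_axis <- function(b) {
  fills <- rowSums(b)
  n <- nrow(b)
  shared <- tcrossprod(b)                 # shared[i, j] = presences in common
  pair_min <- outer(fills, fills, pmin)
  differs <- outer(fills, fills, `!=`)
  contrib <- ifelse(differs & pair_min > 0, 100 * shared / pair_min, 0)
  sum(contrib[upper.tri(contrib)])
}

#' NODF nestedness of an interaction matrix
#'
#' Nestedness metric based on Overlap and Decreasing Fill. The matrix is
#' binarised (presence = count > 0) and empty rows and columns are dropped.
#' For every unordered pair of rows, the pair contributes
#' `100 * (shared presences) / (fill of the poorer row)` when the two row
#' fills differ, and 0 when they are equal ("decreasing fill"); column pairs
#' contribute analogously. NODF is the mean contribution over all
#' `n(n-1)/2 + m(m-1)/2` pairs, so it ranges from 0 (e.g. any matrix whose
#' rows and columns all have equal fills) to 100 (a strictly nested
#' matrix). The value is invariant to row and column permutations.
#'
#' @param m Numeric matrix of counts or presences, rows = hosts,
#'   columns = visitors. At least two non-empty rows and two non-empty
#'   columns are required.
#' @return Real in `[0, 100]`.
#' @examples
#' nodf(rbind(c(1, 1, 1), c(1, 1, 0), c(1, 0, 0))) # 100
#' nodf(diag(2))                                   # 0
#' @export
nodf <- function(m) {
  b <- (as.matrix(m) > 0) * 1
  b <- b[rowSums(b) > 0, colSums(b) > 0, drop = FALSE]
  if (nrow(b) < 2 || ncol(b) < 2) {
    stop("NODF needs at least two non-empty rows and two non-empty columns",
         call. = FALSE)
  }
  n <- nrow(b)
  p <- ncol(b)
  n_pairs <- n * (n - 1) / 2 + p * (p - 1) / 2
  (nodf_axis(b) + nodf_axis(t(b))) / n_pairs
}

#' Isocline of perfect nestedness
#'
#' The boundary a perfectly nested matrix with the same fill would have,
#' drawn in the coordinates of the count matrix with rows and columns sorted
#' by decreasing totals (as produced by [to_matrix()]). Overlaying this
#' curve on the observed matrix shows how far the community departs from
#' perfect nestedness: in a perfectly nested community every presence lies
#' above/left of the isocline.
#'
#' The curve used is `y(x) = nrow * (1 - x / ncol)^p` with
#' `p = 1/fill - 1`, a smooth monotone non-increasing boundary whose
#' enclosed area is exactly `fill * nrow * ncol`.
#'
#' @param shape Integer pair `(rows, cols)` of the matrix.
#' @param fill Fraction of realised cells, strictly between 0 and 1.
#' @param n_points Number of sampled points along the curve.
#' @return Data frame with columns `x` (column coordinate, 0..cols) and `y`
#'   (row coordinate, 0..rows), non-increasing in `x`.
#' @export
isocline_perfect_nestedness <- function(shape, fill, n_points = 200) {
  stopifnot(length(shape) == 2, shape[1] >= 1, shape[2] >= 1, n_points >= 2)
  if (fill <= 0 || fill >= 1) {
    stop("fill must lie strictly between 0 and 1", call. = FALSE)
  }
  r <- shape[1]
  cc <- shape[2]
  p <- 1 / fill - 1
  x <- seq(0, cc, length.out = n_points)
  data.frame(x = x, y = r * (1 - x / cc)^p)
}

#' Distinct-partner count of every node
#'
#' @param net An [build_network()] object.
#' @return Named integer vector over all nodes (hosts and visitors): the
#'   number of distinct partners each interacts with.
#' @export
partner_counts <- function(net) {
  host_deg <- table(net$edges$host_id)
  vis_deg <- table(net$edges$visitor_id)
  counts <- c(as.integer(host_deg[net$host_ids]),
              as.integer(vis_deg[net$visitor_ids]))
  names(counts) <- c(net$host_ids, net$visitor_ids)
  counts
}

#' Frequency distribution of the number of interactions per node
#'
#' How common well-connected versus poorly-connected species are: for each
#' node its number of interactions (distinct partners; repeat events with
#' the same partner are weights on the edge, not extra interactions), then
#' the frequency of each value over all nodes.
#'
#' @param net An [build_network()] object.
#' @return Named integer vector: names are partner counts, values the number
#'   of nodes with that count. Values sum to the number of nodes.
#' @export
interaction_frequency_distribution <- function(net) {
  counts <- partner_counts(net)
  tab <- table(counts)
  out <- as.integer(tab)
  names(out) <- names(tab)
  out
}

#' In- and out-degree distributions
#'
#' Arcs point from host to visitor, so hosts carry out-degrees and visitors
#' in-degrees. The sums of in- and out-degrees both equal the number of
#' links.
#'
#' @param net An [build_network()] object.
#' @return List with named integer vectors `in_degree` (visitor degrees) and
#'   `out_degree` (host degrees), each a frequency table of degree values.
#' @export
degree_distributions <- function(net) {
  as_hist <- function(tab) {
    out <- as.integer(tab)
    names(out) <- names(tab)
    out
  }
  list(
    in_degree = as_hist(table(as.integer(table(net$edges$visitor_id)))),
    out_degree = as_hist(table(as.integer(table(net$edges$host_id))))
  )
}

#' Power-law exponent of a degree histogram
#'
#' Fits `log(frequency) ~ log(degree)` by unweighted least squares over the
#' non-zero bins and returns the slope. Scale-free-like networks give a
#' negative slope (frequencies decreasing in degree).
#'
#' @param hist Named numeric vector: names are degree values, entries
#'   frequencies. At least three distinct positive degrees with positive
#'   frequency are required.
#' @return The fitted slope.
#' @examples
#' k <- c(1, 2, 4, 8)
#' power_law_fit(stats::setNames(k^-2, k)) # -2
#' @export
power_law_fit <- function(hist) {
  k <- as.numeric(names(hist))
  f <- as.numeric(hist)
  keep <- k > 0 & f > 0
  k <- k[keep]
  f <- f[keep]
  if (length(unique(k)) < 3) {
    stop("power-law fit needs at least three distinct positive degrees",
         call. = FALSE)
  }
  unname(stats::coef(stats::lm(log(f) ~ log(k)))[2])
}

#' Dependence values of every link, in one direction
#'
#' @param net An [build_network()] object.
#' @param direction `"host_on_visitor"` (how much each host depends on each
#'   of its visitors) or `"visitor_on_host"`.
#' @return Numeric vector in `(0, 1]`, one entry per link.
#' @export
dependence_values <- function(net,
                              direction = c("host_on_visitor",
                                            "visitor_on_host")) {
  direction <- match.arg(direction)
  if (nrow(net$edges) == 0) return(numeric(0))
  key <- if (direction == "host_on_visitor") "host_id" else "visitor_id"
  totals <- tapply(net$edges$count, net$edges[[key]], sum)
  net$edges$count / as.numeric(totals[net$edges[[key]]])
}

#' Relative-frequency distribution of dependence values
#'
#' Bins the [dependence_values()] of one direction on a fixed partition of
#' `(0, 1]` and returns relative frequencies (summing to 1). In mutualistic
#' webs most dependences are weak, with a secondary mode at 1 from species
#' that rely on a single partner.
#'
#' @inheritParams dependence_values
#' @param bins Number of equal-width bins over `[0, 1]`, `>= 2`.
#' @return Data frame with columns `lower`, `upper` and `rel_freq`.
#' @export
dependence_distribution <- function(net,
                                    direction = c("host_on_visitor",
                                                  "visitor_on_host"),
                                    bins = 10) {
  stopifnot(bins >= 2)
  vals <- dependence_values(net, direction)
  if (length(vals) == 0) {
    stop("dependence distribution is undefined for an empty network",
         call. = FALSE)
  }
  breaks <- seq(0, 1, length.out = bins + 1)
  idx <- cut(vals, breaks = breaks, labels = FALSE, right = TRUE)
  counts <- tabulate(idx, nbins = bins)
  data.frame(lower = breaks[-(bins + 1)], upper = breaks[-1],
             rel_freq = counts / length(vals))
}

#' Mean interaction-frequency distribution over replicate networks
#'
#' Averages the [interaction_frequency_distribution()] over several
#' networks: for each partner-count value, the mean and standard deviation
#' (across networks) of the number of nodes with that count.
#'
#' @param nets List of [build_network()] objects.
#' @return Data frame with columns `partners`, `mean_freq`, `sd_freq`.
#' @export
aggregate_interaction_frequencies <- function(nets) {
  hists <- lapply(nets, interaction_frequency_distribution)
  degrees <- sort(unique(as.integer(unlist(lapply(hists, names)))))
  freq <- vapply(hists, function(h) {
    f <- numeric(length(degrees))
    f[match(as.integer(names(h)), degrees)] <- as.numeric(h)
    f
  }, numeric(length(degrees)))
  freq <- matrix(freq, nrow = length(degrees))
  data.frame(
    partners = degrees,
    mean_freq = rowMeans(freq),
    sd_freq = apply(freq, 1, stats::sd)
  )
}

#' Full structural report of a network
#'
#' Bundles the structural descriptors of one interaction network: species
#' and link counts, connectance, NODF nestedness, the interaction-frequency
#' and degree distributions with the fitted power-law slope, the dependence
#' distributions in both directions, and the isocline of perfect nestedness
#' for the network's shape and fill. NODF and the slope are `NA` when the
#' network is too small or degenerate for them.
#'
#' @param net An [build_network()] object with at least one edge.
#' @param bins Bin count for the dependence distributions.
#' @return An object of class `metrics_report` (a list).
#' @export
metrics_report <- function(net, bins = 10) {
  if (nrow(net$edges) == 0) {
    stop("metrics are undefined for an empty network", call. = FALSE)
  }
  m <- to_matrix(net)
  ifd <- interaction_frequency_distribution(net)
  total_degree_hist <- stats::setNames(as.numeric(ifd),
                                       names(ifd))
  fill <- nrow(net$edges) / (nrow(m) * ncol(m))
  rep <- list(
    S = length(net$host_ids) + length(net$visitor_ids),
    L = nrow(net$edges),
    n_events = net$n_events,
    connectance = connectance(net),
    nodf = tryCatch(nodf(m), error = function(e) NA_real_),
    interaction_freq = ifd,
    degree_dist = degree_distributions(net),
    power_law_slope = tryCatch(power_law_fit(total_degree_hist),
                               error = function(e) NA_real_),
    dependence_hist = list(
      host_on_visitor = dependence_distribution(net, "host_on_visitor", bins),
      visitor_on_host = dependence_distribution(net, "visitor_on_host", bins)
    ),
    isocline = if (fill > 0 && fill < 1) {
      isocline_perfect_nestedness(dim(m), fill)
    } else {
      NULL
    }
  )
  structure(rep, class = "metrics_report")
}

#' @export
print.metrics_report <- function(x, ...) {
  cat(sprintf(
    "<metrics_report> S=%d L=%d events=%d C=%.4f NODF=%.3f slope=%.3f\n",
    x$S, x$L, x$n_events, x$connectance, x$nodf, x$power_law_slope))
  invisible(x)
}

#' Serialise a metrics report to JSON
#'
#' @param report A [metrics_report()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metrics_json <- function(report, path) {
  doc <- list(
    S = report$S, L = report$L, n_events = report$n_events,
    connectance = report$connectance, nodf = report$nodf,
    power_law_slope = report$power_law_slope,
    interaction_freq = list(
      partners = as.integer(names(report$interaction_freq)),
      n_nodes = as.integer(report$interaction_freq)
    ),
    degree_dist = list(
      in_degree = list(
        degree = as.integer(names(report$degree_dist$in_degree)),
        n_nodes = as.integer(report$degree_dist$in_degree)
      ),
      out_degree = list(
        degree = as.integer(names(report$degree_dist$out_degree)),
        n_nodes = as.integer(report$degree_dist$out_degree)
      )
    ),
    dependence_hist = report$dependence_hist,
    isocline = report$isocline
  )
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
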