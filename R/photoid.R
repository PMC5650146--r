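# Photo-ID bookkeeping: capture histories for marked individuals, marked
# proportion per primary period, discovery curve, site-fidelity bins and
# group-size summaries.

#' Compile capture histories for marked individuals
#'
#' One binary detection array per distinct marked ID: cell (t, k) is 1 iff
#' the individual has at least one sighting record in primary t, secondary
#' k. Duplicate records collapse; unmarked rows (blank ID) are excluded.
#' The mean detection location per primary is retained for the spatial
#' model.
#'
#' @param sightings a \code{sighting_table} (see \code{simulate_captures}
#'   for the column contract).
#' @param n_primary,n_secondary design dimensions; defaults taken from the
#'   data maxima.
#' @return object of class \code{capture_history_set}: \code{det}
#'   (n x T x K binary array), \code{locs} (n x T x 2 mean detection
#'   locations, NA where undetected), \code{n_det} (n x T counts),
#'   \code{ids}.
#' @export
build_capture_histories <- function(sightings,
                                    n_primary = max(sightings$primary),
                                    n_secondary = max(sightings$secondary)) {
  marked <- sightings[!is.na(sightings$id) & nzchar(sightings$id), ,
                      drop = FALSE]
  if (nrow(marked)) {
    if (any(marked$primary < 1 | marked$primary > n_primary |
            marked$secondary < 1 | marked$secondary > n_secondary) ||
        any(marked$primary != floor(marked$primary)))
      stop("malformed primary/secondary indices")
  }
  ids <- sort(unique(marked$id))
  n <- length(ids)
  det <- array(0L, dim = c(n, n_primary, n_secondary),
               dimnames = list(ids, NULL, NULL))
  locs <- array(NA_real_, dim = c(n, n_primary, 2))
  ss <- matrix(0, n, n_primary)
  if (n) {
    i <- match(marked$id, ids)
    det[cbind(i, marked$primary, marked$secondary)] <- 1L
    for (t in seq_len(n_primary)) {
      sel <- marked$primary == t
      if (!any(sel)) next
      mx <- tapply(marked$x[sel], marked$id[sel], mean)
      my <- tapply(marked$y[sel], marked$id[sel], mean)
      # within-primary scatter of the detection locations (both axes):
      # carries the direct information on the location/detection scale
      ssq <- tapply(seq_len(sum(sel)), marked$id[sel], function(ix) {
        xx <- marked$x[sel][ix]; yy <- marked$y[sel][ix]
        sum((xx - mean(xx))^2) + sum((yy - mean(yy))^2)
      })
      j <- match(names(mx), ids)
      locs[cbind(j, t, 1)] <- as.numeric(mx)
      locs[cbind(j, t, 2)] <- as.numeric(my)
      ss[cbind(j, t)] <- as.numeric(ssq)
    }
  }
  structure(list(det = det, locs = locs, ss = ss,
                 n_det = apply(det, c(1, 2), sum), ids = ids,
                 n_primary = n_primary, n_secondary = n_secondary),
            class = "capture_history_set")
}

#' @export
print.capture_history_set <- function(x, ...) {
  cat(sprintf("capture_history_set: %d individuals, %d primaries x %d secondaries\n",
              length(x$ids), x$n_primary, x$n_secondary))
  invisible(x)
}

#' Marked proportion and its binomial SE for one primary period
#'
#' The proportion of photographed dolphins with distinctive (D1/D2) fins.
#' Total density is later obtained by dividing marked-animal density by
#' this proportion; the inflation factor 1/p is returned alongside.
#' Rows flagged as calves (a logical \code{calf} column, if present) are
#' excluded from the denominator.
#'
#' @param sightings a \code{sighting_table}.
#' @param primary primary period index.
#' @return one-row data.frame: primary, marked, photographed, proportion,
#'   se, inflation.
#' @export
marked_proportion <- function(sightings, primary) {
  s <- sightings[sightings$primary == primary, , drop = FALSE]
  if (!is.null(s$calf)) s <- s[!s$calf, , drop = FALSE]
  # photographed = distinct marked individuals + unmarked sighting records
  marked_ids <- unique(s$id[nzchar(s$id)])
  n_marked <- length(marked_ids)
  n_unmarked <- sum(!nzchar(s$id))
  n_photo <- n_marked + n_unmarked
  if (n_photo == 0L) stop(sprintf("no photographed dolphins in primary %d",
                                  primary))
  p <- n_marked / n_photo
  data.frame(primary = primary, marked = n_marked, photographed = n_photo,
             proportion = p, se = sqrt(p * (1 - p) / n_photo),
             inflation = if (p > 0) 1 / p else NA_real_)
}

#' Marked proportion table for all primaries
#' @export
marked_proportion_table <- function(sightings) {
  do.call(rbind, lapply(sort(unique(sightings$primary)),
                        function(t) marked_proportion(sightings, t)))
}

#' Discovery curve of new marked individuals
#'
#' Cumulative count of distinct marked individuals first identified by each
#' primary period; monotone nondecreasing with final value equal to the
#' catalog size.
#'
#' @param histories a \code{capture_history_set}.
#' @return integer vector of length n_primary.
#' @export
discovery_curve <- function(histories) {
  if (histories$n_primary < 1L) stop("need >= 1 primary")
  seen <- histories$n_det > 0
  if (!length(histories$ids)) return(rep(0L, histories$n_primary))
  first <- apply(seen, 1, function(r) which(r)[1])
  cumsum(tabulate(first, nbins = histories$n_primary))
}

#' Site-fidelity bins from number of primaries sighted
#'
#' Individuals sighted in 1-2 primary periods are low site fidelity (LSF),
#' 3-4 moderate (MSF), 5 or more high (HSF); edges are configurable for
#' designs other than the default 8-primary one.
#'
#' @param histories a \code{capture_history_set}.
#' @param edges c(max primaries for LSF, max primaries for MSF).
#' @return factor (LSF/MSF/HSF) named by individual ID.
#' @export
site_fidelity_bins <- function(histories, edges = c(2L, 4L)) {
  n_prim_seen <- rowSums(histories$n_det > 0)
  if (any(n_prim_seen == 0))
    stop("individual with zero detections violates the history invariant")
  bin <- ifelse(n_prim_seen <= edges[1], "LSF",
                ifelse(n_prim_seen <= edges[2], "MSF", "HSF"))
  factor(stats::setNames(bin, histories$ids), levels = c("LSF", "MSF", "HSF"))
}

#' Group-size summaries by season and per-primary tallies
#'
#' @param sightings a \code{sighting_table}.
#' @param season_map named character vector mapping primary index (as
#'   character) to season label.
#' @return list with \code{by_season} (season, n_groups, mean_size, se) and
#'   \code{by_primary} (primary, n_groups, n_records, n_marked_ids).
#' @export
summarize_sightings <- function(sightings, season_map) {
  if (is.null(names(season_map))) stop("season_map must be named by primary")
  miss <- setdiff(as.character(unique(sightings$primary)), names(season_map))
  if (length(miss)) stop("season_map missing primaries: ",
                         paste(miss, collapse = ", "))
  g <- sightings[!duplicated(sightings$group_id), , drop = FALSE]
  g$season <- season_map[as.character(g$primary)]
  by_season <- do.call(rbind, lapply(split(g, g$season), function(d) {
    n <- nrow(d)
    data.frame(season = d$season[1], n_groups = n,
               mean_size = mean(d$group_size),
               se = if (n > 1) stats::sd(d$group_size) / sqrt(n) else NA_real_)
  }))
  empties <- setdiff(unique(season_map), g$season)
  if (length(empties)) warning("seasons with no groups omitted: ",
                               paste(empties, collapse = ", "))
  by_primary <- do.call(rbind, lapply(split(sightings, sightings$primary),
                                      function(d) {
    data.frame(primary = d$primary[1],
               n_groups = length(unique(d$group_id)),
               n_records = nrow(d),
               n_marked_ids = length(unique(d$id[nzchar(d$id)])))
  }))
  rownames(by_season) <- rownames(by_primary) <- NULL
  list(by_season = by_season, by_primary = by_primary)
}

#' Export capture histories as a long event CSV (one row per detection)
#' @export
write_history_events_csv <- function(histories, path) {
  idx <- which(histories$det == 1L, arr.ind = TRUE)
  df <- data.frame(id = histories$ids[idx[, 1]],
                   primary = idx[, 2], secondary = idx[, 3])
  df <- df[order(df$id, df$primary, df$secondary), ]
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Export capture histories as a wide CSV (ID x occasion)
#' @export
write_histories_csv <- function(histories, path) {
  Tn <- histories$n_primary; K <- histories$n_secondary
  flat <- matrix(histories$det, nrow = length(histories$ids))
  colnames(flat) <- as.vector(outer(seq_len(Tn), seq_len(K),
                                    function(t, k) sprintf("p%d_s%d", t, k)))
  # det array dims (n, T, K) flatten column-major: col index = (k-1)*T + t
  df <- data.frame(id = histories$ids, flat, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
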