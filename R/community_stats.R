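# Statistical layer: log-log Pearson correlations, per-date Kendall
# concordance, 0-5 day lagged correlations, the thresholded date-node
# correlation network, and checklist concordance with bootstrap CIs.

#' Log-log Pearson correlation with a one-tailed p-value
#'
#' Pearson correlation of `log(x + pseudocount)` against
#' `log(y + pseudocount)`, used when abundances span orders of magnitude.
#' The one-tailed p-value for positive association comes from the t
#' transform with n - 2 degrees of freedom. Zero variance after the log
#' transform is flagged as undefined rather than propagating NaN.
#'
#' @param x,y Non-negative numeric vectors of equal length >= 3.
#' @param pseudocount Added before logging so structural zeros are
#'   representable (default 1).
#' @param lag_days Optional day-lag annotation copied into the result.
#' @return One-row data frame: `kind`, `estimate`, `p_one_tail`, `n`,
#'   `lag_days`, `undefined`.
#' @export
loglog_pearson <- function(x, y, pseudocount = 1, lag_days = NA_integer_) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  if (any(x < 0) || any(y < 0)) stop("inputs must be non-negative")
  lx <- log(x + pseudocount)
  ly <- log(y + pseudocount)
  res <- data.frame(kind = "pearson_loglog", estimate = NA_real_,
                    p_one_tail = NA_real_, n = n, lag_days = lag_days,
                    undefined = FALSE)
  if (stats::sd(lx) == 0 || stats::sd(ly) == 0) {
    res$undefined <- TRUE
    return(res)
  }
  r <- stats::cor(lx, ly)
  tstat <- r * sqrt((n - 2) / (1 - r^2))
  res$estimate <- r
  res$p_one_tail <- stats::pt(tstat, df = n - 2, lower.tail = FALSE)
  res
}

#' Kendall tau-b concordance with a one-tailed p-value
#'
#' Tie-corrected Kendall correlation (via [stats::cor.test()]) with the
#' one-tailed alternative of positive association. Constant input is flagged
#' as undefined.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @param lag_days Optional day-lag annotation.
#' @return One-row data frame: `kind`, `estimate`, `p_one_tail`, `n`,
#'   `lag_days`, `undefined`.
#' @export
kendall_tau <- function(x, y, lag_days = NA_integer_) {
  stopifnot(length(x) == length(y))
  n <- length(x)
  if (n < 3) stop("need at least 3 paired observations")
  res <- data.frame(kind = "kendall", estimate = NA_real_,
                    p_one_tail = NA_real_, n = n, lag_days = lag_days,
                    undefined = FALSE)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    res$undefined <- TRUE
    return(res)
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "kendall",
                                         alternative = "greater"))
  res$estimate <- unname(ct$estimate)
  res$p_one_tail <- ct$p.value
  res
}

shared_taxa <- function(a, b) intersect(colnames(a), colnames(b))
shared_dates <- function(a, b) intersect(rownames(a), rownames(b))

#' Per-species time-course correlations of eDNA reads vs survey counts
#'
#' For each taxon present in both matrices, the log-log Pearson correlation
#' of standardized reads against survey counts across shared dates, with a
#' one-tailed significance flag at `alpha` and a Benjamini-Hochberg adjusted
#' column for transparency (not used in the significance flag).
#'
#' @param reads,surveys [community_matrix()] objects sharing >= 3 dates.
#' @param pseudocount Passed to [loglog_pearson()].
#' @param alpha One-tailed significance level (default 0.05).
#' @return Data frame with one row per shared taxon: `taxon`, `estimate`,
#'   `p_one_tail`, `p_bh`, `n`, `undefined`, `significant`.
#' @export
per_species_timecourse <- function(reads, surveys, pseudocount = 1,
                                   alpha = 0.05) {
  dates <- shared_dates(reads, surveys)
  if (length(dates) < 3) stop("need at least 3 shared dates")
  taxa <- shared_taxa(reads, surveys)
  skipped <- setdiff(union(colnames(reads), colnames(surveys)), taxa)
  if (length(skipped) > 0) {
    message("taxa present on one side only, skipped: ",
            paste(skipped, collapse = ", "))
  }
  rows <- lapply(taxa, function(tx) {
    r <- loglog_pearson(reads[dates, tx], surveys[dates, tx],
                        pseudocount = pseudocount)
    data.frame(taxon = tx, estimate = r$estimate,
               p_one_tail = r$p_one_tail, n = r$n, undefined = r$undefined)
  })
  out <- do.call(rbind, rows)
  out$p_bh <- stats::p.adjust(out$p_one_tail, method = "BH")
  out$significant <- !out$undefined & !is.na(out$p_one_tail) &
    out$p_one_tail < alpha
  out[, c("taxon", "estimate", "p_one_tail", "p_bh", "n", "undefined",
          "significant")]
}

#' Cross-species Kendall concordance on one date
#'
#' Kendall tau-b across shared taxa between standardized reads and survey
#' counts on a given date, with a one-tailed p-value.
#'
#' @param reads,surveys [community_matrix()] objects.
#' @param date The date (present in both matrices).
#' @return One-row data frame as from [kendall_tau()], plus a `date` column.
#' @export
per_date_kendall <- function(reads, surveys, date) {
  date <- as.character(as.Date(date))
  if (!date %in% rownames(reads) || !date %in% rownames(surveys)) {
    stop("date ", date, " absent from one of the matrices")
  }
  taxa <- shared_taxa(reads, surveys)
  if (length(taxa) < 3) {
    stop("fewer than 3 shared taxa on ", date, "; refusing to correlate")
  }
  res <- kendall_tau(reads[date, taxa], surveys[date, taxa])
  cbind(date = date, res)
}

#' Lagged correlations between eDNA reads and daily surveys
#'
#' For each day-lag l in 0..`max_lag`, correlates the eDNA community on
#' sampling date t against the surveys on date t - l: per date across shared
#' taxa (Kendall tau-b) and per taxon across dates (log-log Pearson).
#' Lagged dates with no survey are skipped and recorded.
#'
#' @param reads [community_matrix()] on sampling dates.
#' @param surveys [community_matrix()] at (ideally daily) calendar
#'   resolution.
#' @param max_lag Maximum look-back in days (default 5).
#' @param pseudocount Passed to [loglog_pearson()].
#' @return List with `per_date` (data frame `lag_days`, `date`,
#'   `survey_date`, `estimate`, `p_one_tail`, `n`, `undefined`),
#'   `per_species` (data frame `lag_days`, `taxon`, `estimate`,
#'   `p_one_tail`, `n`, `undefined`) and `skipped` (data frame `lag_days`,
#'   `date`, `survey_date`).
#' @export
lagged_correlations <- function(reads, surveys, max_lag = 5,
                                pseudocount = 1) {
  if (max_lag < 0) stop("max_lag must be >= 0")
  taxa <- shared_taxa(reads, surveys)
  if (length(taxa) < 3) stop("need at least 3 shared taxa")
  read_dates <- as.Date(rownames(reads))
  survey_dates <- rownames(surveys)

  per_date <- list()
  per_species <- list()
  skipped <- list()
  for (lag in 0:max_lag) {
    lagged <- as.character(read_dates - lag)
    have <- lagged %in% survey_dates
    for (i in which(!have)) {
      skipped[[length(skipped) + 1L]] <- data.frame(
        lag_days = lag, date = as.character(read_dates[i]),
        survey_date = lagged[i])
    }
    for (i in which(have)) {
      res <- kendall_tau(reads[as.character(read_dates[i]), taxa],
                         surveys[lagged[i], taxa], lag_days = lag)
      per_date[[length(per_date) + 1L]] <- cbind(
        date = as.character(read_dates[i]), survey_date = lagged[i],
        res[, c("lag_days", "estimate", "p_one_tail", "n", "undefined")])
    }
    if (sum(have) >= 3) {
      for (tx in taxa) {
        res <- loglog_pearson(reads[have, tx],
                              surveys[lagged[have], tx],
                              pseudocount = pseudocount, lag_days = lag)
        per_species[[length(per_species) + 1L]] <- cbind(
          taxon = tx,
          res[, c("lag_days", "estimate", "p_one_tail", "n", "undefined")])
      }
    }
  }
  bind0 <- function(x, proto) if (length(x)) do.call(rbind, x) else proto
  list(
    per_date = bind0(per_date, data.frame(
      date = character(0), survey_date = character(0),
      lag_days = integer(0), estimate = numeric(0),
      p_one_tail = numeric(0), n = integer(0), undefined = logical(0))),
    per_species = bind0(per_species, data.frame(
      taxon = character(0), lag_days = integer(0), estimate = numeric(0),
      p_one_tail = numeric(0), n = integer(0), undefined = logical(0))),
    skipped = bind0(skipped, data.frame(
      lag_days = integer(0), date = character(0),
      survey_date = character(0))))
}

#' Correlation-based network of dated community snapshots
#'
#' Nodes are (date, layer) pairs for the visual and eDNA layers; candidate
#' edges are all visual-visual date pairs and all visual-eDNA date pairs
#' (eDNA-eDNA pairs only when `include_edna_edges = TRUE`). An edge is kept
#' iff the log-log Pearson correlation of the two community vectors across
#' shared taxa has r >= `threshold` and one-tailed p < `alpha`.
#'
#' @param visual,reads [community_matrix()] objects with >= 2 dates and
#'   >= 3 shared taxa.
#' @param threshold Minimum correlation coefficient in (0, 1]
#'   (default 0.6).
#' @param alpha One-tailed significance level (default 0.05).
#' @param pseudocount Passed to [loglog_pearson()].
#' @param include_edna_edges Also test eDNA-eDNA date pairs
#'   (default FALSE).
#' @return List with `graph` (an [igraph::graph][igraph] with vertex
#'   attributes `date`, `layer` and edge attributes `weight` = r, `p`) and
#'   `edges` (data frame `from`, `to`, `r`, `p`).
#' @export
build_network <- function(visual, reads, threshold = 0.6, alpha = 0.05,
                          pseudocount = 1, include_edna_edges = FALSE) {
  if (!(threshold > 0 && threshold <= 1)) {
    stop("threshold must be in (0, 1]")
  }
  taxa <- shared_taxa(visual, reads)
  if (length(taxa) < 3) stop("need at least 3 shared taxa")
  if (nrow(visual) < 2 || nrow(reads) < 2) stop("need at least 2 dates")

  nodes <- rbind(
    data.frame(name = paste0("visual:", rownames(visual)),
               date = rownames(visual), layer = "visual"),
    data.frame(name = paste0("eDNA:", rownames(reads)),
               date = rownames(reads), layer = "eDNA"))
  vec <- function(node) {
    layer <- sub(":.*$", "", node)
    date <- sub("^[^:]*:", "", node)
    if (layer == "visual") visual[date, taxa] else reads[date, taxa]
  }

  cand <- list()
  vn <- nodes$name[nodes$layer == "visual"]
  en <- nodes$name[nodes$layer == "eDNA"]
  if (length(vn) >= 2) {
    cp <- utils::combn(vn, 2)
    cand <- c(cand, lapply(seq_len(ncol(cp)), function(i) cp[, i]))
  }
  cand <- c(cand, unlist(lapply(vn, function(a) {
    lapply(en, function(b) c(a, b))
  }), recursive = FALSE))
  if (include_edna_edges && length(en) >= 2) {
    cp <- utils::combn(en, 2)
    cand <- c(cand, lapply(seq_len(ncol(cp)), function(i) cp[, i]))
  }

  edges <- list()
  for (pair in cand) {
    if (pair[1] == pair[2]) next
    res <- loglog_pearson(vec(pair[1]), vec(pair[2]),
                          pseudocount = pseudocount)
    if (!res$undefined && !is.na(res$estimate) &&
        res$estimate >= threshold && res$estimate > 0 &&
        res$p_one_tail < alpha) {
      edges[[length(edges) + 1L]] <- data.frame(
        from = pair[1], to = pair[2], r = res$estimate, p = res$p_one_tail)
    }
  }
  edges <- if (length(edges)) do.call(rbind, edges) else
    data.frame(from = character(0), to = character(0), r = numeric(0),
               p = numeric(0))

  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  if (nrow(edges) > 0) {
    igraph::E(g)$weight <- edges$r
  }
  list(graph = g, edges = edges, threshold = threshold, alpha = alpha)
}

#' Checklist concordance: eDNA vs focal vs community checklists
#'
#' For each date with at least `min_checklists` checklists: (a) Kendall
#' tau-b between the focal survey and each checklist, with the mean and a
#' seeded percentile bootstrap 95% CI over checklists; (b) Kendall tau-b
#' between standardized reads and the focal survey; (c) whether (b) exceeds
#' the mean of (a). Dates with fewer checklists are excluded.
#'
#' @param checklists Checklist data frame (`checklist_id`, `date`,
#'   `species`, `count`).
#' @param focal [community_matrix()] of focal counts.
#' @param reads [community_matrix()] of standardized reads.
#' @param dates Dates to evaluate (default: all focal dates).
#' @param min_checklists Minimum checklists per included date (default 3).
#' @param n_boot Bootstrap resamples (default 1000).
#' @param seed Seed for the bootstrap.
#' @param pools Species pools applied to the checklist means so taxon names
#'   match the pooled focal/eDNA matrices (default
#'   [default_species_pools()]).
#' @return Data frame with one row per included date: `date`,
#'   `n_checklists`, `mean_tau_checklist`, `ci_lo`, `ci_hi`, `tau_edna`,
#'   `edna_exceeds_mean`.
#' @export
checklist_concordance <- function(checklists, focal, reads, dates = NULL,
                                  min_checklists = 3, n_boot = 1000,
                                  seed = 1L,
                                  pools = default_species_pools()) {
  checklists$date <- as.Date(checklists$date)
  if (is.null(dates)) dates <- as.Date(rownames(focal))
  dates <- as.Date(dates)
  set.seed(seed)
  rows <- list()
  for (d in as.character(dates)) {
    cl <- checklists[checklists$date == as.Date(d), , drop = FALSE]
    ids <- unique(cl$checklist_id)
    if (length(ids) < min_checklists || !(d %in% rownames(focal)) ||
        !(d %in% rownames(reads))) {
      next
    }
    # per-checklist community vectors over the pooled species universe
    cl_mats <- lapply(ids, function(id) {
      one <- cl[cl$checklist_id == id, , drop = FALSE]
      v <- stats::setNames(one$count, one$species)
      v
    })
    species <- sort(unique(cl$species))
    cl_vecs <- lapply(cl_mats, function(v) {
      full <- stats::setNames(numeric(length(species)), species)
      full[names(v)] <- v
      pool_vector(full, pools)
    })
    taxa <- intersect(names(cl_vecs[[1]]), colnames(focal))
    taxa <- intersect(taxa, colnames(reads))
    if (length(taxa) < 3) next
    fv <- focal[d, taxa]
    taus <- vapply(cl_vecs, function(v) {
      res <- kendall_tau(fv, v[taxa])
      if (res$undefined) NA_real_ else res$estimate
    }, numeric(1))
    taus_ok <- taus[!is.na(taus)]
    if (length(taus_ok) == 0L) next
    boot_means <- vapply(seq_len(n_boot), function(b) {
      mean(sample(taus_ok, replace = TRUE))
    }, numeric(1))
    ci <- stats::quantile(boot_means, c(0.025, 0.975), names = FALSE)
    te <- kendall_tau(reads[d, taxa], fv)
    rows[[length(rows) + 1L]] <- data.frame(
      date = d, n_checklists = length(ids),
      mean_tau_checklist = mean(taus_ok), ci_lo = ci[1], ci_hi = ci[2],
      tau_edna = te$estimate,
      edna_exceeds_mean = !is.na(te$estimate) &&
        te$estimate > mean(taus_ok))
  }
  if (length(rows) == 0L) {
    return(data.frame(date = character(0), n_checklists = integer(0),
                      mean_tau_checklist = numeric(0), ci_lo = numeric(0),
                      ci_hi = numeric(0), tau_edna = numeric(0),
                      edna_exceeds_mean = logical(0)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# pool a named species vector the same way pool_taxa pools matrix columns
pool_vector <- function(v, pools) {
  for (pair in pools) {
    present <- pair[pair %in% names(v)]
    if (length(present) == 0L) next
    pooled_name <- paste(pair, collapse = "/")
    pooled <- sum(v[present])
    v <- v[setdiff(names(v), present)]
    v[pooled_name] <- pooled
  }
  v
}
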