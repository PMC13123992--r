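# Synthetic-data generator: migration abundance trajectories, visual and
# checklist surveys, reference sequences with embedded primer-binding sites,
# and Dirichlet-multinomial ASV read tables with negative controls. All
# randomness flows from one root seed through named substreams so each stage
# is independently reproducible.

derive_seed <- function(root_seed, stream) {
  h <- sum(utf8ToInt(stream) * seq_along(utf8ToInt(stream)))
  as.integer((as.numeric(root_seed) * 10007 + h * 97) %% 2147483587)
}

with_substream <- function(root_seed, stream, expr) {
  if (exists(".Random.seed", envir = globalenv())) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(derive_seed(root_seed, stream))
  expr
}

random_nt <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# resolve each degenerate position uniformly at random to one concrete base
resolve_degenerate <- function(primer) {
  masks <- iupac_masks(primer)
  bases <- vapply(masks, function(m) {
    opts <- c("A", "C", "G", "T")[bitwAnd(m, c(1L, 2L, 4L, 8L)) != 0L]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
  paste0(bases, collapse = "")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) return(rep(1 / length(alpha), length(alpha)))
  g / sum(g)
}

#' Default waterfowl species parameters for simulation
#'
#' A roster of 17 North American waterfowl species spanning the three
#' tribe groups targeted by the ND2 primer pairs, with Gaussian passage
#' parameters producing the early-dabbler / late-diver turnover typical of
#' fall migration and peak abundances spanning several orders of magnitude
#' (8 to 5000 individuals).
#'
#' @return Data frame with columns `species`, `genus`, `family`, `tribe`,
#'   `class`, `peak_date`, `passage_width`, `peak_abundance`,
#'   `shedding_factor`.
#' @export
default_species_params <- function() {
  sp <- function(species, tribe, peak, width, abund, shed = 1) {
    data.frame(species = species,
               genus = strsplit(species, " ")[[1]][1],
               family = "Anatidae", tribe = tribe, class = "Aves",
               peak_date = as.Date(peak), passage_width = width,
               peak_abundance = abund, shedding_factor = shed)
  }
  ans <- "Anserini/Cygnini"
  ana <- "Anatini/Cairinini/Oxyura"
  ayt <- "Aythyini/Mergini"
  do.call(rbind, list(
    sp("Branta canadensis",   ans, "2020-10-10", 14, 5000),
    sp("Anser caerulescens",  ans, "2020-11-15", 10, 3000),
    sp("Cygnus columbianus",  ans, "2020-11-20",  9,  200),
    sp("Cygnus buccinator",   ans, "2020-11-18", 10,   40),
    sp("Anas platyrhynchos",  ana, "2020-10-05", 13, 1500),
    sp("Anas rubripes",       ana, "2020-10-20", 12,  300),
    sp("Anas crecca",         ana, "2020-09-28",  9,  800),
    sp("Anas acuta",          ana, "2020-10-12", 10,  400),
    sp("Aix sponsa",          ana, "2020-09-25",  8,  150),
    sp("Mareca penelope",     ana, "2020-10-18",  9,    8),
    sp("Oxyura jamaicensis",  ana, "2020-11-05", 11,  600),
    sp("Aythya marila",       ayt, "2020-11-12",  9,  120),
    sp("Aythya affinis",      ayt, "2020-11-08", 10,  250),
    sp("Aythya collaris",     ayt, "2020-11-02", 11,  900),
    sp("Aythya valisineria",  ayt, "2020-11-16",  9, 1000),
    sp("Bucephala albeola",   ayt, "2020-11-10",  8,  300),
    sp("Lophodytes cucullatus", ayt, "2020-11-06", 9,  60)
  ))
}

#' Build and validate a simulation configuration
#'
#' Defaults follow the field design being emulated: 10 weekly sampling dates
#' during fall migration (late September to late November), 3 field
#' replicates plus a field blank per date, ~650,000 reads per sample, and a
#' 6-weight kernel spreading each date's eDNA signal over the sampling day
#' and the 5 days before it.
#'
#' @param seed Root integer seed; every stochastic stage derives its own
#'   substream from it.
#' @param dates Ordered sampling dates.
#' @param species Species parameter table (see [default_species_params()]).
#' @param detection_prob Per-individual detection probability for visual
#'   observers, in (0, 1].
#' @param observer_dispersion Negative-binomial dispersion of observer
#'   counts; 0 gives Poisson counts.
#' @param read_depth_per_sample Total reads per field sample.
#' @param read_overdispersion Dirichlet-multinomial overdispersion of read
#'   shares; 0 gives pure multinomial sampling.
#' @param lag_kernel Six non-negative weights over day-lags 0..5 summing
#'   to 1.
#' @param contamination_rate Probability that an ASV appears in any given
#'   negative-control sample, in [0, 1).
#' @param n_field_replicates Field water replicates per date.
#' @param n_negatives Number of extraction blanks and of PCR blanks.
#' @param asvs_per_species Number of ASVs each species emits.
#' @param n_decoys Non-target (fish/mammal) reference records.
#' @param checklists_per_date Integer vector recycled over survey dates
#'   giving checklists per date (mix of values below and at/above 3 so the
#'   at-least-3-checklists analyses are exercised).
#' @param lookback_days Days before each sampling date on which checklist
#'   surveys are also generated.
#' @param distractors Add extra ASVs whose hit profiles exercise the
#'   tie/exclusion branches of taxonomic assignment.
#' @return A validated `simulation_config` list.
#' @export
simulation_config <- function(seed = 1L,
                              dates = as.Date("2020-09-24") + 7 * (0:9),
                              species = default_species_params(),
                              detection_prob = 0.8,
                              observer_dispersion = 0.5,
                              read_depth_per_sample = 650000L,
                              read_overdispersion = 0.05,
                              lag_kernel = c(0.35, 0.25, 0.17, 0.11,
                                             0.07, 0.05),
                              contamination_rate = 0.02,
                              n_field_replicates = 3L,
                              n_negatives = 2L,
                              asvs_per_species = 2L,
                              n_decoys = 5L,
                              checklists_per_date = c(4L, 1L, 3L, 5L, 2L,
                                                      4L, 1L, 3L, 4L, 5L),
                              lookback_days = 5L,
                              distractors = TRUE) {
  cfg <- list(seed = as.integer(seed), dates = as.Date(dates),
              species = species, detection_prob = detection_prob,
              observer_dispersion = observer_dispersion,
              read_depth_per_sample = read_depth_per_sample,
              read_overdispersion = read_overdispersion,
              lag_kernel = lag_kernel,
              contamination_rate = contamination_rate,
              n_field_replicates = as.integer(n_field_replicates),
              n_negatives = as.integer(n_negatives),
              asvs_per_species = as.integer(asvs_per_species),
              n_decoys = as.integer(n_decoys),
              checklists_per_date = as.integer(checklists_per_date),
              lookback_days = as.integer(lookback_days),
              distractors = isTRUE(distractors))
  validate_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_config <- function(cfg) {
  if (length(cfg$dates) == 0L) stop("invalid config: empty date list")
  if (is.null(cfg$species) || nrow(cfg$species) == 0L) {
    stop("invalid config: empty species list")
  }
  sp <- cfg$species
  if (any(sp$passage_width <= 0)) stop("passage_width must be > 0")
  if (any(sp$peak_abundance < 0)) stop("peak_abundance must be >= 0")
  if (any(sp$shedding_factor <= 0)) stop("shedding_factor must be > 0")
  ok_tribes <- c("Anserini/Cygnini", "Anatini/Cairinini/Oxyura",
                 "Aythyini/Mergini")
  if (!all(sp$tribe %in% ok_tribes)) {
    stop("unknown tribe(s): ",
         paste(setdiff(unique(sp$tribe), ok_tribes), collapse = ", "))
  }
  if (anyDuplicated(sp$species)) stop("duplicate species names")
  if (!(cfg$detection_prob > 0 && cfg$detection_prob <= 1)) {
    stop("detection_prob must be in (0, 1]")
  }
  if (cfg$observer_dispersion < 0) stop("observer_dispersion must be >= 0")
  if (any(cfg$read_depth_per_sample <= 0)) {
    stop("read_depth_per_sample must be > 0")
  }
  if (cfg$read_overdispersion < 0) stop("read_overdispersion must be >= 0")
  k <- cfg$lag_kernel
  if (length(k) != 6L || any(k < 0) || abs(sum(k) - 1) > 1e-9) {
    stop("lag_kernel must be 6 non-negative weights summing to 1")
  }
  if (!(cfg$contamination_rate >= 0 && cfg$contamination_rate < 1)) {
    stop("contamination_rate must be in [0, 1)")
  }
  if (cfg$n_field_replicates < 1L) stop("n_field_replicates must be >= 1")
  if (cfg$n_negatives < 1L) stop("n_negatives must be >= 1")
  invisible(cfg)
}

# Deterministic Gaussian passage abundance at arbitrary dates.
abundance_values <- function(species, dates) {
  out <- sapply(seq_len(nrow(species)), function(i) {
    dt <- as.numeric(dates - species$peak_date[i])
    round(species$peak_abundance[i] *
            exp(-dt^2 / (2 * species$passage_width[i]^2)))
  })
  out <- matrix(out, nrow = length(dates),
                dimnames = list(as.character(dates), species$species))
  out
}

#' Simulate true migration abundances
#'
#' Each species follows a Gaussian passage curve: the abundance on date `t`
#' is `round(peak_abundance * exp(-(t - peak_date)^2 / (2 passage_width^2)))`.
#' Deterministic given the configuration.
#'
#' @param config A [simulation_config()].
#' @param dates Dates to evaluate (default the config's sampling dates; pass
#'   a daily grid for lagged analyses).
#' @return A [community_matrix()] with provenance `"truth"`.
#' @export
simulate_abundance <- function(config, dates = config$dates) {
  validate_config(config)
  community_matrix(abundance_values(config$species, as.Date(dates)),
                   provenance = "truth")
}

#' Simulate visual surveys and community checklists
#'
#' One focal (exhaustive) survey per sampling date plus a configurable
#' number of independent checklists per survey date (sampling dates and
#' their look-back days). Each observer's count for a (date, species) cell
#' is negative-binomial with mean `detection_prob * abundance` and
#' dispersion `observer_dispersion` (Poisson at dispersion 0).
#'
#' @param truth Truth matrix from [simulate_abundance()] (used for
#'   validation and returned for test use).
#' @param config A [simulation_config()].
#' @return List with `focal` (data frame `date`, `species`, `count`),
#'   `checklists` (`checklist_id`, `date`, `species`, `count`) and the input
#'   `truth`.
#' @export
simulate_surveys <- function(truth, config) {
  validate_config(config)
  check_truth_alignment(truth, config)
  draw_counts <- function(mu, n = length(mu)) {
    if (config$observer_dispersion == 0) {
      stats::rpois(n, lambda = mu)
    } else {
      stats::rnbinom(n, mu = mu, size = 1 / config$observer_dispersion)
    }
  }
  with_substream(config$seed, "surveys", {
    species <- config$species$species
    focal <- do.call(rbind, lapply(seq_along(config$dates), function(i) {
      ab <- abundance_values(config$species, config$dates[i])[1, ]
      data.frame(date = config$dates[i], species = species,
                 count = draw_counts(config$detection_prob * ab))
    }))

    lookback <- unlist(lapply(config$dates,
                              function(d) d - seq_len(config$lookback_days)))
    survey_dates <- sort(unique(c(config$dates, as.Date(lookback,
                                                        origin = "1970-01-01"))))
    n_cl <- rep_len(config$checklists_per_date, length(survey_dates))
    cl_rows <- list()
    cl_counter <- 0L
    for (i in seq_along(survey_dates)) {
      ab <- abundance_values(config$species, survey_dates[i])[1, ]
      for (j in seq_len(n_cl[i])) {
        cl_counter <- cl_counter + 1L
        cl_rows[[cl_counter]] <- data.frame(
          checklist_id = sprintf("CL%05d", cl_counter),
          date = survey_dates[i], species = species,
          count = draw_counts(config$detection_prob * ab))
      }
    }
    list(focal = focal, checklists = do.call(rbind, cl_rows), truth = truth)
  })
}

check_truth_alignment <- function(truth, config) {
  if (!identical(rownames(truth), as.character(config$dates)) ||
      !identical(colnames(truth), config$species$species)) {
    stop("truth matrix does not align with the configuration's ",
         "dates/species")
  }
  invisible(TRUE)
}

decoy_lineage <- function(n) {
  pool <- data.frame(
    species = c("Micropterus salmoides", "Lepomis macrochirus",
                "Salmo trutta", "Perca flavescens", "Esox lucius",
                "Castor canadensis", "Ondatra zibethicus",
                "Procyon lotor"),
    family = c("Centrarchidae", "Centrarchidae", "Salmonidae", "Percidae",
               "Esocidae", "Castoridae", "Cricetidae", "Procyonidae"),
    class = c(rep("Actinopterygii", 5), rep("Mammalia", 3)))
  idx <- rep_len(seq_len(nrow(pool)), n)
  out <- pool[idx, ]
  out$genus <- vapply(strsplit(out$species, " "), `[`, character(1), 1L)
  rownames(out) <- NULL
  out
}

#' Simulate a reference sequence set with embedded primer-binding sites
#'
#' One record per species: random background flanks around an exact
#' forward-primer site (a concrete expansion of the species' tribe-matched
#' degenerate primer), an insert of that pair's expected length, and the
#' reverse complement of a concrete reverse-primer expansion. Non-target
#' decoy records (fish/mammals) are rejection-sampled to carry no primer
#' site within 2 mismatches of any pair.
#'
#' @param config A [simulation_config()].
#' @param max_attempts Rejection-sampling bound per record.
#' @return List with `sequences` (named character vector) and `lineage`
#'   (data frame `record_id`, `species`, `genus`, `family`, `tribe`,
#'   `class`).
#' @export
simulate_references <- function(config, max_attempts = 50L) {
  validate_config(config)
  pairs <- default_primer_pairs()
  with_substream(config$seed, "references", {
    sp <- config$species
    seqs <- character(0)
    for (i in seq_len(nrow(sp))) {
      pair <- pairs[[tribe_pair_name(sp$tribe[i])]]
      rid <- paste0("REF_", gsub(" ", "_", sp$species[i]))
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        s <- paste0(random_nt(sample(60:140, 1)),
                    resolve_degenerate(pair$forward),
                    random_nt(pair$expected_insert),
                    reverse_complement_iupac(resolve_degenerate(pair$reverse)),
                    random_nt(sample(60:140, 1)))
        if (nrow(find_amplicons(pair, s, max_mismatch = 0L)) == 1L) {
          seqs[rid] <- s
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("reference generation failed for ", sp$species[i],
                    " after ", max_attempts, " attempts")
    }

    dec <- decoy_lineage(config$n_decoys)
    dec_ids <- sprintf("DECOY_%02d", seq_len(config$n_decoys))
    for (i in seq_len(config$n_decoys)) {
      ok <- FALSE
      for (attempt in seq_len(max_attempts)) {
        s <- random_nt(sample(400:600, 1))
        hits <- vapply(pairs, function(p) {
          nrow(find_amplicons(p, s, max_mismatch = 2L))
        }, integer(1))
        if (all(hits == 0L)) {
          seqs[dec_ids[i]] <- s
          ok <- TRUE
          break
        }
      }
      if (!ok) stop("decoy generation failed after ", max_attempts,
                    " attempts")
    }

    lineage <- rbind(
      data.frame(record_id = paste0("REF_", gsub(" ", "_", sp$species)),
                 species = sp$species, genus = sp$genus, family = sp$family,
                 tribe = sp$tribe, class = sp$class),
      data.frame(record_id = dec_ids, species = dec$species,
                 genus = dec$genus, family = dec$family,
                 tribe = NA_character_, class = dec$class))
    list(sequences = seqs, lineage = lineage)
  })
}

#' Expected read shares on a sampling date
#'
#' The expected read share of species `s` for the sample taken on date `t`
#' is proportional to
#' `shedding_factor_s * sum_l lag_kernel[l] * abundance(t - l, s)` over
#' day-lags `l` in 0..5.
#'
#' @param config A [simulation_config()].
#' @param date A single date.
#' @return Named numeric vector of shares summing to 1 (all zero when no
#'   species is present in the window).
#' @export
expected_read_shares <- function(config, date) {
  date <- as.Date(date)
  lag_dates <- date - (0:5)
  ab <- abundance_values(config$species, lag_dates)  # 6 x n_species
  w <- config$species$shedding_factor *
    as.numeric(config$lag_kernel %*% ab)
  names(w) <- config$species$species
  if (sum(w) == 0) return(w)
  w / sum(w)
}

#' Simulate an ASV read table with negative controls and a hit table
#'
#' Field-sample read counts are Dirichlet-multinomial draws of
#' `read_depth_per_sample` reads over species (shares from
#' [expected_read_shares()]; pure multinomial at overdispersion 0), split
#' across each species' ASVs by fixed per-species proportions. Negative
#' controls receive sparse geometric contamination. The hit table gives each
#' ASV its true lineage at >= 98% identity plus, optionally, distractor ASVs
#' whose hit profiles exercise the tie and exclusion branches of taxonomic
#' assignment.
#'
#' @param truth Truth matrix from [simulate_abundance()] on the config's
#'   sampling dates.
#' @param config A [simulation_config()].
#' @return List with `counts` (ASV x sample integer matrix), `meta` (sample
#'   metadata: `sample_id`, `date`, `sample_type`, `replicate`), `hits`
#'   (data frame `asv_id`, `subject_species`, `subject_genus`,
#'   `subject_family`, `pct_identity`, `score`), `asv_species` (true ASV to
#'   species map) and the input `truth`.
#' @export
simulate_reads <- function(truth, config) {
  validate_config(config)
  check_truth_alignment(truth, config)
  sp <- config$species
  n_sp <- nrow(sp)
  k <- config$asvs_per_species

  with_substream(config$seed, "reads", {
    asv_ids <- sprintf("ASV_%04d", seq_len(n_sp * k))
    asv_species <- data.frame(asv_id = asv_ids,
                              species = rep(sp$species, each = k))
    asv_props <- lapply(seq_len(n_sp), function(i) {
      if (k == 1L) 1 else rdirichlet1(rep(2, k))
    })

    meta <- list()
    cols <- list()
    for (di in seq_along(config$dates)) {
      d <- config$dates[di]
      shares <- expected_read_shares(config, d)
      for (r in seq_len(config$n_field_replicates)) {
        sid <- sprintf("S%02d_R%d", di, r)
        meta[[sid]] <- data.frame(sample_id = sid, date = d,
                                  sample_type = "field", replicate = r)
        if (sum(shares) == 0) {
          cols[[sid]] <- integer(n_sp * k)
          next
        }
        p <- if (config$read_overdispersion > 0) {
          rdirichlet1(shares / config$read_overdispersion)
        } else shares
        sp_counts <- as.integer(
          stats::rmultinom(1, config$read_depth_per_sample, p))
        cols[[sid]] <- unlist(lapply(seq_len(n_sp), function(i) {
          if (sp_counts[i] == 0L) return(integer(k))
          as.integer(stats::rmultinom(1, sp_counts[i], asv_props[[i]]))
        }))
      }
      sid <- sprintf("S%02d_FB", di)
      meta[[sid]] <- data.frame(sample_id = sid, date = d,
                                sample_type = "field_blank", replicate = NA)
      cols[[sid]] <- integer(n_sp * k)  # contamination added below
    }
    first_date <- config$dates[1]
    blank_ids <- c("FILT_B01",
                   sprintf("EXT_B%02d", seq_len(config$n_negatives)),
                   sprintf("PCR_B%02d", seq_len(config$n_negatives)))
    blank_types <- c("filtration_blank",
                     rep("extraction_blank", config$n_negatives),
                     rep("pcr_blank", config$n_negatives))
    for (b in seq_along(blank_ids)) {
      meta[[blank_ids[b]]] <- data.frame(sample_id = blank_ids[b],
                                         date = first_date,
                                         sample_type = blank_types[b],
                                         replicate = NA)
      cols[[blank_ids[b]]] <- integer(n_sp * k)
    }

    counts <- do.call(cbind, cols)
    rownames(counts) <- asv_ids
    meta <- do.call(rbind, meta)
    rownames(meta) <- NULL

    # sparse geometric contamination in every blank column
    blank_cols <- which(meta$sample_type != "field")
    for (j in blank_cols) {
      present <- stats::runif(nrow(counts)) < config$contamination_rate
      counts[present, j] <- counts[present, j] +
        as.integer(stats::rgeom(sum(present), prob = 0.4)) + 1L
    }

    # hit table: true species >= 98%, plus in-genus and sub-98 distractor
    # hits that never outrank the true hit
    hit_rows <- lapply(seq_len(nrow(asv_species)), function(i) {
      s <- sp[match(asv_species$species[i], sp$species), ]
      top_id <- round(stats::runif(1, 98.3, 99.9), 1)
      rows <- data.frame(asv_id = asv_species$asv_id[i],
                         subject_species = s$species,
                         subject_genus = s$genus,
                         subject_family = s$family,
                         pct_identity = top_id,
                         score = round(top_id * 5, 1))
      genus_mates <- setdiff(sp$species[sp$genus == s$genus], s$species)
      if (length(genus_mates) > 0) {
        id2 <- round(top_id - stats::runif(1, 0.6, 1.8), 1)
        rows <- rbind(rows, data.frame(
          asv_id = asv_species$asv_id[i],
          subject_species = sample(genus_mates, 1),
          subject_genus = s$genus, subject_family = s$family,
          pct_identity = id2, score = round(id2 * 5, 1)))
      }
      id3 <- round(stats::runif(1, 90, 95), 1)
      rbind(rows, data.frame(asv_id = asv_species$asv_id[i],
                             subject_species = "Gallus gallus",
                             subject_genus = "Gallus",
                             subject_family = "Phasianidae",
                             pct_identity = id3, score = round(id3 * 5, 1)))
    })
    hits <- do.call(rbind, hit_rows)

    if (config$distractors) {
      extra <- distractor_asvs(counts, meta)
      counts <- rbind(counts, extra$counts)
      hits <- rbind(hits, extra$hits)
    }

    list(counts = counts, meta = meta, hits = hits,
         asv_species = asv_species, truth = truth)
  })
}

# Extra ASVs exercising assignment branches: genus tie, family tie,
# cross-family exclusion, and an ASV with no hits at all.
distractor_asvs <- function(counts, meta) {
  field_cols <- which(meta$sample_type == "field")
  ids <- c("ASV_TIE_GENUS", "ASV_TIE_FAMILY", "ASV_EXCLUDED", "ASV_NOHITS")
  extra <- matrix(0L, nrow = length(ids), ncol = ncol(counts),
                  dimnames = list(ids, colnames(counts)))
  picked <- field_cols[seq_len(min(3L, length(field_cols)))]
  extra[, picked] <- matrix(
    as.integer(stats::rpois(length(ids) * length(picked), 15)),
    nrow = length(ids))
  hits <- rbind(
    data.frame(asv_id = "ASV_TIE_GENUS",
               subject_species = c("Anas platyrhynchos", "Anas rubripes"),
               subject_genus = "Anas", subject_family = "Anatidae",
               pct_identity = 99.0, score = 495.0),
    data.frame(asv_id = "ASV_TIE_FAMILY",
               subject_species = c("Anas crecca", "Aythya collaris"),
               subject_genus = c("Anas", "Aythya"),
               subject_family = "Anatidae",
               pct_identity = 98.5, score = 492.5),
    data.frame(asv_id = "ASV_EXCLUDED",
               subject_species = c("Gallus gallus", "Salmo trutta"),
               subject_genus = c("Gallus", "Salmo"),
               subject_family = c("Phasianidae", "Salmonidae"),
               pct_identity = 91.0, score = 455.0))
  list(counts = extra, hits = hits)
}

#' Run the full synthetic-data generator
#'
#' Convenience wrapper chaining [simulate_abundance()], [simulate_surveys()],
#' [simulate_references()] and [simulate_reads()] from one configuration.
#'
#' @param config A [simulation_config()].
#' @return List with `truth`, `surveys`, `references`, `reads` and the
#'   `config` itself.
#' @export
simulate_dataset <- function(config) {
  truth <- simulate_abundance(config)
  list(truth = truth,
       surveys = simulate_surveys(truth, config),
       references = simulate_references(config),
       reads = simulate_reads(truth, config),
       config = config)
}
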