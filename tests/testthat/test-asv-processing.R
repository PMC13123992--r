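# Taxonomic assignment, control filtering, depth standardization,
# aggregation and checklist means.

hit_row <- function(asv, sp, genus, fam, id, score = id * 5) {
  data.frame(asv_id = asv, subject_species = sp, subject_genus = genus,
             subject_family = fam, pct_identity = id, score = score)
}

# small table: 4 ASVs x (2 field dates x 2 replicates + blanks)
toy_table <- function(counts = NULL) {
  if (is.null(counts)) {
    counts <- rbind(
      ASV_A = c(100L, 120L, 200L, 180L, 0L, 8L, 2L),
      ASV_B = c(3L,   1L,   0L,   1L,  0L, 0L, 0L),
      ASV_C = c(50L,  40L,  10L,  0L,  1L, 2L, 0L),
      ASV_D = c(0L,   2L,   1L,   0L,  0L, 0L, 0L))
  }
  colnames(counts) <- c("S1_R1", "S1_R2", "S2_R1", "S2_R2",
                        "FB1", "EXT1", "PCR1")
  meta <- data.frame(
    sample_id = colnames(counts),
    date = as.Date(c("2020-10-01", "2020-10-01", "2020-10-08",
                     "2020-10-08", "2020-10-01", "2020-10-01",
                     "2020-10-01")),
    sample_type = c("field", "field", "field", "field", "field_blank",
                    "extraction_blank", "pcr_blank"),
    replicate = c(1, 2, 1, 2, NA, NA, NA))
  asv_table(counts, meta)
}

test_that("assignment resolves every branch of the identity/LCA rule", {
  hits <- rbind(
    # single species at >= 98% -> species
    hit_row("ASV1", "Anas acuta", "Anas", "Anatidae", 99.1),
    hit_row("ASV1", "Anas crecca", "Anas", "Anatidae", 96.0),
    # two species of one genus tied at >= 98% -> genus
    hit_row("ASV2", "Anas platyrhynchos", "Anas", "Anatidae", 99.0),
    hit_row("ASV2", "Anas rubripes", "Anas", "Anatidae", 99.0),
    # two genera of one family tied -> family
    hit_row("ASV3", "Anas crecca", "Anas", "Anatidae", 98.4),
    hit_row("ASV3", "Aythya collaris", "Aythya", "Anatidae", 98.4),
    # ties spanning families -> excluded
    hit_row("ASV4", "Gallus gallus", "Gallus", "Phasianidae", 91.0),
    hit_row("ASV4", "Salmo trutta", "Salmo", "Salmonidae", 91.0),
    # sub-98% single species -> falls back to genus, never species
    hit_row("ASV5", "Aythya marila", "Aythya", "Anatidae", 95.5))
  out <- assign_taxonomy(hits, asv_ids = paste0("ASV", 1:6))
  out <- out[match(paste0("ASV", 1:6), out$asv_id), ]
  expect_identical(out$rank,
                   c("species", "genus", "family", "excluded", "genus",
                     "excluded"))
  expect_identical(out$name[1:3], c("Anas acuta", "Anas", "Anatidae"))
  expect_identical(out$basis,
                   c("single_species_ge98", "tie_lca_genus",
                     "tie_lca_family", "below_family_excluded",
                     "sub98_lca_genus", "no_hits"))
  expect_identical(out$best_identity[1], 99.1)
  # totality: one assignment per ASV
  expect_identical(nrow(out), 6L)
})

test_that("only the top five hits by (score, identity) are considered", {
  # five dominant hits on one species; a sixth, lower-scoring hit ties the
  # best identity with another species and would force a genus call if it
  # were not truncated away
  hits <- rbind(
    do.call(rbind, lapply(1:5, function(i) {
      hit_row("ASVX", "Anas acuta", "Anas", "Anatidae", 99.0,
              score = 500 - i)
    })),
    hit_row("ASVX", "Anas crecca", "Anas", "Anatidae", 99.0, score = 400))
  out <- assign_taxonomy(hits)
  expect_identical(out$rank, "species")
  expect_identical(out$name, "Anas acuta")
})

test_that("assignment validates identities", {
  expect_error(assign_taxonomy(
    hit_row("A", "x", "y", "z", 101)), "pct_identity")
})

test_that("control threshold averages the non-zero per-ASV control sums", {
  # control sums per ASV: {10, 0, 2, 0} -> mean of {10, 2} = 6
  counts <- rbind(
    ASV_A = c(10L, 10L, 10L, 10L, 0L, 4L, 6L),
    ASV_B = c(9L,  9L,  9L,  9L,  0L, 0L, 0L),
    ASV_C = c(80L, 80L, 80L, 80L, 0L, 2L, 0L),
    ASV_D = c(7L,  7L,  7L,  7L,  0L, 0L, 0L))
  tab <- toy_table(counts)
  expect_identical(control_filter_threshold(tab), 6)
  # per-control alternative: non-zero control totals {6, 6} -> 6
  expect_identical(control_filter_threshold(tab, mode = "per_control"), 6)
  # all-zero controls give threshold 0
  counts0 <- counts
  counts0[, 6:7] <- 0L
  expect_identical(control_filter_threshold(toy_table(counts0)), 0)
  # a single contaminated ASV: mean of one value
  counts1 <- counts0
  counts1["ASV_B", 7] <- 7L
  expect_identical(control_filter_threshold(toy_table(counts1)), 7)
  # no controls at all is a configuration error
  tab_nc <- tab
  keep <- tab$meta$sample_type %in% c("field", "field_blank")
  tab_nc <- asv_table(tab$counts[, keep], tab$meta[keep, ])
  expect_error(control_filter_threshold(tab_nc), "cannot be computed")
})

test_that("the control filter removes strictly-below-threshold ASVs", {
  tab <- toy_table()
  # field totals: A = 600, B = 5, C = 100, D = 3
  f0 <- apply_control_filter(tab, 0)
  expect_identical(rownames(f0$counts), rownames(tab$counts))
  expect_message(f5 <- apply_control_filter(tab, 5), "1 ASV")
  expect_identical(attr(f5, "removed_asvs"), "ASV_D")
  # at exactly the threshold the ASV is retained ("fewer than" is strict)
  suppressMessages({
    expect_true("ASV_B" %in% rownames(apply_control_filter(tab, 5)$counts))
    expect_false("ASV_B" %in% rownames(apply_control_filter(tab, 6)$counts))
    # worked threshold 6 removes exactly the ASVs with field totals < 6
    f6 <- apply_control_filter(tab, 6)
  })
  expect_setequal(rownames(f6$counts), c("ASV_A", "ASV_C"))
  # blank columns carried through untouched
  expect_identical(f6$counts[, "EXT1"], tab$counts[c(1, 3), "EXT1"])
})

test_that("filtering is monotone in the threshold", {
  set.seed(610)
  for (i in 1:20) {
    counts <- matrix(rpois(4 * 7, 10), nrow = 4,
                     dimnames = list(paste0("ASV_", 1:4), NULL))
    tab <- toy_table(counts)
    kept_prev <- NULL
    for (thr in c(0, 20, 40, 80)) {
      kept <- rownames(suppressMessages(
        apply_control_filter(tab, thr))$counts)
      if (!is.null(kept_prev)) expect_true(all(kept %in% kept_prev))
      kept_prev <- kept
    }
  }
})

test_that("depth standardization scales every field sample to the minimum", {
  tab <- toy_table()
  std <- standardize_depth(tab)
  fc <- which(std$meta$sample_type == "field")
  depths <- colSums(tab$counts[, fc])
  d_min <- min(depths)
  expect_equal(unname(colSums(std$counts[, fc])), rep(d_min, length(fc)),
               tolerance = 1e-6)
  expect_identical(attr(std, "min_depth"), d_min)
  # blanks untouched
  bc <- which(std$meta$sample_type != "field")
  expect_equal(std$counts[, bc], tab$counts[, bc] * 1.0)
  # two samples at depths 1000 and 500: a count of 8 in the deeper one
  # scales to 4
  counts <- rbind(ASV_A = c(8L, 100L), ASV_B = c(992L, 400L))
  colnames(counts) <- c("S1_R1", "S2_R1")
  meta <- data.frame(sample_id = colnames(counts),
                     date = as.Date(c("2020-10-01", "2020-10-08")),
                     sample_type = "field", replicate = 1)
  std2 <- standardize_depth(asv_table(counts, meta))
  expect_identical(unname(std2$counts["ASV_A", "S1_R1"]), 4)
  # equal depths: identity
  counts_eq <- rbind(ASV_A = c(10L, 10L), ASV_B = c(20L, 20L))
  colnames(counts_eq) <- c("S1_R1", "S2_R1")
  std_eq <- standardize_depth(asv_table(counts_eq, meta))
  expect_equal(std_eq$counts, counts_eq * 1.0)
  # idempotence
  std_twice <- standardize_depth(std)
  expect_equal(std_twice$counts, std$counts, tolerance = 1e-12)
})

test_that("aggregation to dates conserves reads and pools pairs", {
  tab <- toy_table()
  assignments <- data.frame(
    asv_id = c("ASV_A", "ASV_B", "ASV_C", "ASV_D"),
    rank = c("species", "species", "species", "excluded"),
    name = c("Anas platyrhynchos", "Anas rubripes", "Aythya collaris",
             NA),
    best_identity = 99, basis = "single_species_ge98")
  cm <- suppressMessages(
    aggregate_to_dates(tab, assignments, pools = list()))
  fc <- which(tab$meta$sample_type == "field")
  kept <- c("ASV_A", "ASV_B", "ASV_C")
  expect_equal(sum(cm), sum(tab$counts[kept, fc]), tolerance = 1e-9)
  expect_identical(rownames(cm), c("2020-10-01", "2020-10-08"))
  # replicate summation: date value is the sum over that date's replicates
  expect_equal(unname(cm["2020-10-01", "Anas platyrhynchos"]), 220)
  # pooling merges the pair and conserves the total
  cm_pooled <- suppressMessages(aggregate_to_dates(tab, assignments))
  expect_true("Anas platyrhynchos/Anas rubripes" %in% colnames(cm_pooled))
  expect_equal(sum(cm_pooled), sum(cm), tolerance = 1e-9)
  expect_equal(cm_pooled[, "Anas platyrhynchos/Anas rubripes"],
               cm[, "Anas platyrhynchos"] + cm[, "Anas rubripes"])
  # equal replicate columns triple the single-replicate value
  counts3 <- cbind(S1_R1 = c(10L, 5L), S1_R2 = c(10L, 5L),
                   S1_R3 = c(10L, 5L))
  rownames(counts3) <- c("ASV_A", "ASV_B")
  meta3 <- data.frame(sample_id = colnames(counts3),
                      date = as.Date("2020-10-01"),
                      sample_type = "field", replicate = 1:3)
  cm3 <- suppressMessages(aggregate_to_dates(
    asv_table(counts3, meta3), assignments, pools = list()))
  expect_equal(unname(cm3[1, "Anas platyrhynchos"]), 30)
})

test_that("pooling a taxon absent from the table is a logged no-op", {
  m <- matrix(1:4, 2, dimnames = list(c("2020-10-01", "2020-10-08"),
                                      c("Anas acuta", "Aix sponsa")))
  expect_message(out <- pool_taxa(m, list(c("Cygnus buccinator",
                                            "Cygnus columbianus"))),
                 "no member present")
  expect_identical(unclass(out), unclass(m))
})

test_that("checklist means use the absent-as-zero rule", {
  cl <- data.frame(
    checklist_id = c("C1", "C1", "C2", "C3"),
    date = as.Date(c("2020-10-01", "2020-10-01", "2020-10-01",
                     "2020-10-08")),
    species = c("Anas acuta", "Aix sponsa", "Anas acuta", "Anas acuta"),
    count = c(10, 4, 0, 7))
  cm <- checklist_means(cl)
  # {10, 0} across the two checklists -> 5
  expect_identical(unname(cm["2020-10-01", "Anas acuta"]), 5)
  # species absent from one of two checklists: {4, 0} -> 2
  expect_identical(unname(cm["2020-10-01", "Aix sponsa"]), 2)
  # single checklist: counts verbatim; unobserved species 0
  expect_identical(unname(cm["2020-10-08", "Anas acuta"]), 7)
  expect_identical(unname(cm["2020-10-08", "Aix sponsa"]), 0)
  expect_identical(unname(attr(cm, "n_checklists")),
                   c(2L, 1L))
  expect_warning(checklist_means(cl, dates = as.Date(c("2020-10-01",
                                                       "2020-12-01"))),
                 "no checklists")
})

test_that("the one-call pipeline recovers proportional truth", {
  # no observation noise sources: delta kernel, equal shedding, no
  # contamination, pure multinomial reads -> standardized community is
  # proportional to truth per date within sampling error
  cfg <- simulation_config(seed = 640,
                           species = default_species_params()[c(1, 5, 7,
                                                                14, 16), ],
                           lag_kernel = c(1, 0, 0, 0, 0, 0),
                           read_overdispersion = 0,
                           contamination_rate = 0,
                           read_depth_per_sample = 200000L,
                           distractors = FALSE)
  truth <- simulate_abundance(cfg)
  reads <- simulate_reads(truth, cfg)
  res <- suppressMessages(process_asv_table(
    asv_table(reads$counts, reads$meta), reads$hits, pools = list()))
  expect_identical(res$threshold, 0)
  expect_identical(res$n_removed, 0L)
  cm <- res$community
  for (d in rownames(cm)) {
    tr <- truth[d, colnames(cm)]
    if (sum(tr) == 0) next
    got <- cm[d, ] / sum(cm[d, ])
    want <- tr / sum(tr)
    expect_lt(max(abs(got - want)), 0.02)
  }
})
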