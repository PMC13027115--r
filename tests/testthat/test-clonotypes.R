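mkSamples <- function(ids, patient, group, tissue = "blood",
                      timepoint = "Pre") {
  data.frame(sample_id = ids, patient = patient, group = group,
             tissue = tissue, timepoint = timepoint,
             stringsAsFactors = FALSE)
}

mkAnn <- function(sample_id, cell_id, locus = "TRB", v_call = "TRBV27*01",
                  j_call = "TRBJ2*01", cdr3_aa = "CASSLGQAYEQYF") {
  data.frame(sample_id = sample_id, cell_id = cell_id, locus = locus,
             v_call = v_call, j_call = j_call, cdr3_aa = cdr3_aa,
             productive = TRUE, stringsAsFactors = FALSE)
}

test_that("clonotype calling aggregates cells by locus, V gene and CDR3", {
  samples <- mkSamples("S1", "P01", "MSS")
  ann <- rbind(mkAnn("S1", "c1"), mkAnn("S1", "c2"), mkAnn("S1", "c3"))
  tab <- callClonotypes(ann, samples)
  expect_equal(nrow(tab), 1L)
  expect_equal(unname(SummarizedExperiment::assay(tab, "cells")[1, 1]), 3L)
  # same CDR3 but different V gene -> distinct clonotypes
  ann2 <- rbind(ann, mkAnn("S1", "c4", v_call = "TRBV6-5*01"))
  tab2 <- callClonotypes(ann2, samples)
  expect_equal(nrow(tab2), 2L)
  # allele differences collapse to the same key
  ann3 <- rbind(ann, mkAnn("S1", "c4", v_call = "TRBV27*02"))
  expect_equal(nrow(callClonotypes(ann3, samples)), 1L)
  # a cell contributes once per key regardless of extra contigs
  ann4 <- rbind(ann, mkAnn("S1", "c1"))
  expect_equal(unname(SummarizedExperiment::assay(
    callClonotypes(ann4, samples), "cells")[1, 1]), 3L)
  # unknown sample is an error
  expect_error(callClonotypes(mkAnn("S9", "c1"), samples), "S9")
})

test_that("clonotype keys recovered from simulated truth match the truth", {
  ref <- sharedRef()
  cfg <- smallSimConfig(seed = 61L, n_clonotypes_per_sample = 10L)
  sim <- simulateRepertoire(cfg, ref, tempfile())
  tab <- callClonotypes(sim$truth, sim$samples)
  truth_keys <- unique(paste(sim$truth$locus,
                             sub("\\*.*$", "", sim$truth$v_call),
                             sim$truth$junction_aa))
  got_keys <- paste(SummarizedExperiment::rowData(tab)$locus,
                    SummarizedExperiment::rowData(tab)$v_gene,
                    SummarizedExperiment::rowData(tab)$cdr3_aa)
  expect_setequal(got_keys, truth_keys)
})

test_that("sharing classes follow the patient/group rules and partition", {
  samples <- mkSamples(c("S1", "S4", "S6"), c("P01", "P04", "P06"),
                       c("MSS", "MSI", "MSI"))
  ann <- rbind(
    mkAnn("S1", "c1", cdr3_aa = "CASSPRIVATEF"),
    mkAnn("S4", "c1", cdr3_aa = "CASSINTRAF"),
    mkAnn("S6", "c1", cdr3_aa = "CASSINTRAF"),
    mkAnn("S1", "c2", cdr3_aa = "CASSINTERF"),
    mkAnn("S4", "c2", cdr3_aa = "CASSINTERF"))
  tab <- classifySharing(callClonotypes(ann, samples))
  rd <- as.data.frame(SummarizedExperiment::rowData(tab))
  expect_equal(rd$sharing_class[rd$cdr3_aa == "CASSPRIVATEF"], "private")
  expect_equal(rd$sharing_class[rd$cdr3_aa == "CASSINTRAF"], "intra_group")
  expect_equal(rd$sharing_class[rd$cdr3_aa == "CASSINTERF"], "inter_group")
  expect_equal(sum(table(rd$sharing_class)), nrow(rd))
  # unmapped patient errors
  expect_error(classifySharing(callClonotypes(ann, samples),
                               group_map = c(P01 = "MSS")), "P04")
})

test_that("CDR3 length distribution reports the tie-broken mode", {
  d <- cdr3LengthDistribution(c("CASSLGQAYEQF", "CASSLGQAYEQF",
                                "CASSLGQAYEQYF"))
  expect_equal(d$modal_length, 12L)
  expect_equal(unname(d$histogram[as.character(12)]), 2L)
  d2 <- cdr3LengthDistribution("CASSYEQYF")
  expect_equal(d2$modal_length, 9L)
  expect_equal(unname(d2$histogram), 1L)
  # tie broken to the smaller length
  d3 <- cdr3LengthDistribution(c("CASSYEQYF", "CASSLGQAYEQF"))
  expect_equal(d3$modal_length, 9L)
  expect_error(cdr3LengthDistribution(character(0)), "empty")
})

test_that("positional frequencies and information content behave", {
  # fully conserved columns carry log2(20) bits
  m <- positionalFrequencyMatrix(c("CASSF", "CASSF"))
  expect_equal(unname(m$ic), rep(log2(20), 5), tolerance = 1e-12)
  expect_true(all(abs(rowSums(m$freq) - 1) < 1e-9))
  # a uniform column over all 20 residues has zero information
  aa20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
            "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
  m2 <- positionalFrequencyMatrix(paste0("C", aa20, "F"))
  expect_equal(unname(m2$ic[2]), 0, tolerance = 1e-12)
  # two residues at 0.5 each: log2(20) - 1
  m3 <- positionalFrequencyMatrix(c("CAF", "CGF"))
  expect_equal(unname(m3$ic[2]), log2(20) - 1, tolerance = 1e-12)
  expect_error(positionalFrequencyMatrix(c("CAF", "CAAF")), "length")
})

test_that("V-J pairing counts are restricted, ordered, and biased as built", {
  df <- data.frame(v_gene = c("V1", "V1", "V1", "V2"),
                   j_gene = c("J1", "J1", "J2", "J1"))
  p <- vjPairingMatrix(df, top_n = 30L)
  expect_equal(p$count[p$v_gene == "V1" & p$j_gene == "J1"], 2)
  expect_equal(p$count[1], max(p$count))
  # top_n restriction drops rarer V genes
  p1 <- vjPairingMatrix(df, top_n = 1L)
  expect_true(all(p1$v_gene == "V1"))
  expect_equal(nrow(vjPairingMatrix(df[0, ], top_n = 5L)), 0L)
  # dominance by construction
  set.seed(77)
  big <- data.frame(
    v_gene = sample(c("Va", "Vb"), 300, replace = TRUE, prob = c(.8, .2)),
    j_gene = sample(c("Jb", "Jc"), 300, replace = TRUE, prob = c(.8, .2)))
  pb <- vjPairingMatrix(big, top_n = 10L)
  expect_equal(pb$v_gene[1], "Va")
  expect_equal(pb$j_gene[1], "Jb")
})

test_that("top shared selection ranks by patient count within scope", {
  samples <- mkSamples(
    c("S1n", "S1t", "S2n", "S2t", "S3t"),
    c("P01", "P01", "P02", "P02", "P03"),
    c("MSS", "MSS", "MSS", "MSS", "MSI"),
    tissue = c("normal", "tumor", "normal", "tumor", "tumor"))
  ann <- rbind(
    # in 3 patients, normal+tumor
    mkAnn("S1n", "c1", cdr3_aa = "CASSWIDEF"),
    mkAnn("S1t", "c2", cdr3_aa = "CASSWIDEF"),
    mkAnn("S2n", "c1", cdr3_aa = "CASSWIDEF"),
    mkAnn("S3t", "c1", cdr3_aa = "CASSWIDEF"),
    # in 2 patients, normal+tumor
    mkAnn("S1n", "c3", cdr3_aa = "CASSMIDF"),
    mkAnn("S2t", "c3", cdr3_aa = "CASSMIDF"),
    # tumor only
    mkAnn("S1t", "c4", cdr3_aa = "CASSTUMF"),
    mkAnn("S2t", "c4", cdr3_aa = "CASSTUMF"))
  tab <- classifySharing(callClonotypes(ann, samples))
  top <- selectTopShared(tab, n = 50L, scope = "normal_tumor_shared")
  expect_equal(top$cdr3_aa, c("CASSWIDEF", "CASSMIDF"))  # tumor-only excluded
  expect_equal(top$n_patients, c(3L, 2L))
  expect_equal(top$n_patients_MSI[1], 1L)
  expect_equal(top$n_patients_MSS[1], 2L)
  # n larger than available returns all; n < 1 errors
  expect_equal(nrow(selectTopShared(tab, n = 100L)), 3L)
  expect_error(selectTopShared(tab, n = 0L), "n must be")
  # Sankey edges carry weights per group:tissue
  edges <- sankeyEdges(tab, top)
  expect_true(all(edges$weight > 0))
  expect_true(all(grepl(":", edges$group_tissue_node)))
})

test_that("simulated public pool produces the expected sharing mix", {
  ref <- sharedRef()
  cfg <- simConfig(seed = 71L, n_clonotypes_per_sample = 20L,
                   tissues = "blood", clone_size_param = 1,
                   reads_per_cell_chain = 1L, shared_clone_fraction = 0.3)
  sim <- simulateRepertoire(cfg, ref, tempfile())
  tab <- classifySharing(callClonotypes(sim$truth, sim$samples))
  cls <- SummarizedExperiment::rowData(tab)$sharing_class
  expect_true(sum(cls != "private") > 0)
  expect_true("inter_group" %in% cls)  # pool spans both groups at 30%
  expect_gt(mean(cls == "private"), 0.5)
})
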