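test_that("haplotype windows extend gene spans by the flank", {
  w <- haplotype_window(region("Gm06", 20006928, 20007814))
  expect_equal(c(w$start, w$end), c(20003428, 20011314))
  w2 <- haplotype_window(region("Gm10", 44716804, 44738165))
  expect_equal(c(w2$start, w2$end), c(44713304, 44741665))
  # zero flank is the identity; the start clamps at 1
  expect_equal(haplotype_window(region("Gm06", 10, 20), 0),
               region("Gm06", 10, 20))
  expect_equal(haplotype_window(region("Gm06", 1000, 2000), 3500)$start, 1)
  expect_error(haplotype_window(region("Gm06", 1, 2), -1), "flank")
})

test_that("call_allele maps symbols to allele categories", {
  e1 <- default_allele_registry()[[1]]
  m <- snp_matrix("Gm06", 20007173,
                  c("W82", "S1", "S2", "S3", "S4"),
                  matrix(c("C", "G", "N", "S", "T"), 1, 5))
  calls <- call_allele(m, e1)
  expect_equal(calls$call, c("e1-as", "E1", "no_data", "heterozygous",
                             "unknown_variant"))
  expect_false(attr(calls, "assumed_reference"))
  # exactly one call per sample; categories sum to the sample count
  expect_equal(nrow(calls), length(m$samples))
  expect_equal(sum(table(calls$call)), length(m$samples))
  # missing symbols and only missing symbols give no_data
  expect_equal(calls$call == "no_data", is_missing_symbol(calls$observed))
})

test_that("a registry site absent from the matrix is called assumed-reference", {
  e1 <- default_allele_registry()[[1]]
  m <- mat_from_strings(W82 = "AC", S1 = "AT")  # no 20007173 row
  calls <- call_allele(m, e1)
  expect_true(all(calls$call == "e1-as"))
  expect_true(attr(calls, "assumed_reference"))
  expect_error(call_allele(mat_from_strings(W = "A", S = "C",
                                            chromosome = "Gm10"), e1),
               "chromosome mismatch")
})

test_that("the built-in registry matches the documented causative SNPs", {
  reg <- default_allele_registry()
  key <- vapply(reg, function(d) {
    sprintf("%s:%s:%.0f:%s>%s", d$gene, d$chromosome, d$position,
            d$ref_symbol, d$alt_symbol)
  }, character(1))
  expect_setequal(key, c("E1:Gm06:20007173:C>G",
                         "E2:Gm10:44732850:A>T",
                         "Dt1_R62S:Gm19:44981190:C>A",
                         "Dt1_P113L:Gm19:44980245:G>A",
                         "Dt1_R130K:Gm19:44980194:C>T",
                         "Dt1_R166W:Gm19:44980087:T>A"))
  # registry config file round trip
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# gene chrom pos ref alt ref_name alt_name",
               "E2\tGm10\t44732850\tA\tT\tE2\te2"), f)
  back <- read_allele_registry(f)
  expect_equal(back[[1]]$alt_allele_name, "e2")
  expect_equal(back[[1]]$position, 44732850)
})

test_that("deletion signatures count missing runs and flag by threshold", {
  r <- region("Gm19", 1000, 3000)
  m <- planted_fixture(11, n_samples = 6L, n_sites = 15L, missing = 0)$matrix
  scan <- region("Gm06", min(m$positions), max(m$positions))
  # fully called sample: nothing missing, not flagged
  sig0 <- deletion_signature(m, "S01", scan)
  expect_equal(sig0$n_missing, 0L)
  expect_false(sig0$flagged)
  # plant an all-missing run over 12 of the 15 scan sites
  calls <- m$calls
  calls[1:12, "S02"] <- "-"
  m2 <- snp_matrix(m$chromosome, m$positions, m$samples, calls)
  sig <- deletion_signature(m2, "S02", scan, threshold = 0.9)
  expect_equal(sig$n_sites, 15L)
  expect_equal(sig$n_missing, 12L)
  expect_equal(sig$longest_run, 12L)
  expect_equal(sig$fraction, 0.8)
  expect_false(sig$flagged)                               # 0.8 < 0.9
  expect_true(deletion_signature(m2, "S02", scan, threshold = 0.75)$flagged)
  # all-missing sample is flagged at the default threshold
  calls[, "S03"] <- "-"
  m3 <- snp_matrix(m$chromosome, m$positions, m$samples, calls)
  expect_true(deletion_signature(m3, "S03", scan)$flagged)
  # empty scan region: zero sites, never flagged
  empty <- deletion_signature(m, "S01", region("Gm06", 1, 10))
  expect_equal(empty$n_sites, 0L)
  expect_false(empty$flagged)
})

test_that("deletion fraction ignores the other samples", {
  fx <- planted_fixture(13, n_samples = 8L, n_sites = 20L, missing = 0.3)
  m <- fx$matrix
  scan <- region("Gm06", min(m$positions), max(m$positions))
  before <- deletion_signature(m, "S01", scan)
  calls <- m$calls
  calls[, "S05"] <- "-"
  m2 <- snp_matrix(m$chromosome, m$positions, m$samples, calls)
  after <- deletion_signature(m2, "S01", scan)
  expect_equal(after$fraction, before$fraction)
})

test_that("codon arithmetic follows CDS coordinates", {
  expect_equal(affected_codon(44), 15)
  expect_equal(affected_codon(1561), 521)
  expect_equal(affected_codon(c(1, 2, 3, 4)), c(1, 1, 1, 2))
  expect_error(affected_codon(0), ">= 1")
  expect_equal(frameshift_intact_length(48), 15)
  expect_equal(frameshift_intact_length(1), 0)
  expect_equal(frameshift_intact_length(4), 1)
  # intact length is always one codon less than the affected codon
  p <- 1:300
  expect_equal(frameshift_intact_length(p), affected_codon(p) - 1)
  expect_true(all(diff(affected_codon(p)) >= 0))
  expect_equal(interval_length(47516697, 47519330), 2633)
  expect_equal(interval_length(10, 10), 0)
  expect_equal(interval_length(1, 101), 100)
  expect_error(interval_length(5, 4), ">= start")
})

test_that("genotype_table composes calls over planted alleles", {
  e2 <- default_allele_registry()[[2]]
  base <- planted_fixture(17, n_samples = 10L, n_sites = 30L, missing = 0)$matrix
  m <- snp_matrix("Gm10", base$positions + 44000000, base$samples, base$calls)
  carriers <- c("S02", "S05", "S08")
  m <- plant_allele(m, e2, carriers)
  tab <- genotype_table(m, list(e2))
  expect_equal(nrow(tab), length(m$samples) - 1L)
  expect_setequal(tab$sample[tab$E2 == "e2"], carriers)
  expect_true(all(tab$E2[!tab$sample %in% carriers] == "E2"))
  # an N at the registry site shows up as no_data
  calls <- m$calls
  calls[which(m$positions == e2$position), "S03"] <- "N"
  m2 <- snp_matrix(m$chromosome, m$positions, m$samples, calls)
  tab2 <- genotype_table(m2, list(e2))
  expect_equal(tab2$E2[tab2$sample == "S03"], "no_data")
  # deletion-scan column flags a planted all-missing sample
  calls[, "S07"] <- "-"
  m3 <- snp_matrix(m$chromosome, m$positions, m$samples, calls)
  scan <- region("Gm10", min(m3$positions), max(m3$positions))
  tab3 <- genotype_table(m3, list(e2), e3_scan = scan)
  expect_true(tab3$e3_candidate[tab3$sample == "S07"])
  expect_false(any(tab3$e3_candidate[tab3$sample %in% c("S01", "S02")]))
  # absent site: assumed_reference column names the gene
  m4 <- snp_matrix("Gm10", 1:3 * 100, c("R", "S1"),
                   matrix("A", 3, 2))
  tab4 <- genotype_table(m4, list(e2))
  expect_equal(unique(tab4$assumed_reference), "E2")
})
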