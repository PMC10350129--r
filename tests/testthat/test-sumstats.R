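make_full_table <- function(n = 10, seed = 1) {
  set.seed(seed)
  data.table::data.table(
    CHR = 1L, POS = seq_len(n) * 1000L, SNP = paste0("rs", seq_len(n)),
    A1 = sample(c("A", "C"), n, TRUE), A2 = "G",
    BETA = round(stats::rnorm(n, 0, 0.05), 6),
    SE = round(stats::runif(n, 0.01, 0.05), 6),
    FREQ = round(stats::runif(n, 0.05, 0.95), 4),
    N_EFF = 10000)
}

test_that("write/read round-trip is lossless for shared columns", {
  dt <- make_full_table()
  dt[, P := 2 * stats::pnorm(-abs(BETA / SE))]
  path <- withr::local_tempfile(fileext = ".tsv")
  tab <- symfactor:::new_sumstat(data.table::copy(dt))
  write_sumstats(tab, path)
  back <- read_sumstats(path)
  for (col in c("SNP", "A1", "A2", "BETA", "SE", "FREQ", "N_EFF"))
    expect_equal(back[[col]], dt[[col]], info = col)
})

test_that("ldsc_munged dialect with Z and N only is accepted", {
  path <- withr::local_tempfile(fileext = ".sumstats")
  writeLines(c("SNP\tA1\tA2\tZ\tN", "rs1\tA\tG\t1.5\t5000",
               "rs2\tC\tG\t-0.7\t5000"), path)
  tab <- read_sumstats(path)
  expect_identical(attr(tab, "dialect"), "ldsc_munged")
  expect_equal(tab$Z, c(1.5, -0.7))
})

test_that("invalid rows are rejected with diagnostics", {
  dt <- make_full_table(5)
  dt$SE[3] <- 0
  chk <- validate_sumstats(dt)
  expect_false(chk$ok)
  expect_identical(chk$problems$row, 3L)
  expect_identical(chk$problems$rule, "se_nonpositive")
  path <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(dt, path, sep = "\t")
  expect_warning(tab <- read_sumstats(path), "invalid row")
  expect_equal(nrow(tab), 4)
  path2 <- withr::local_tempfile(fileext = ".tsv")
  data.table::fwrite(dt[, -c("SNP")], path2, sep = "\t")
  expect_error(read_sumstats(path2), "SNP")
})

test_that("harmonization resolves swap, strand, and ambiguity", {
  ref <- data.frame(SNP = paste0("rs", 1:5),
                    A1 = c("A", "A", "A", "G", "C"),
                    A2 = c("G", "G", "T", "C", "A"))
  obs <- symfactor:::new_sumstat(data.table::data.table(
    SNP = paste0("rs", 1:5),
    A1 = c("A", "G", "A", "C", "C"),  # match, swap, palindromic, strand-swap?, match
    A2 = c("G", "A", "T", "G", "A"),
    Z = c(1, 1.5, 2, 2.5, 3), BETA = c(.1, .15, .2, .25, .3),
    N = 1000, FREQ = c(.2, .2, .2, .2, .2)))
  out <- harmonize_sumstats(obs, ref)
  rep <- attr(out, "harmonize_report")
  # rs3 (A/T) and rs4 (C/G palindromic) dropped as ambiguous
  expect_false(any(c("rs3", "rs4") %in% out$SNP))
  expect_equal(rep$ambiguous_dropped, 2L)
  # rs2 swapped: sign flipped, freq complemented
  expect_equal(out[out$SNP == "rs2"]$Z, -1.5)
  expect_equal(out[out$SNP == "rs2"]$FREQ, 0.8)
  expect_equal(out[out$SNP == "rs1"]$Z, 1)
  # output alleles are in reference orientation
  expect_identical(out$A1, ref$A1[match(out$SNP, ref$SNP)])
})

test_that("strand flips resolve via complement with sign by allele match", {
  # non-palindromic G/A variant reported on the other strand as C/T
  ref <- data.frame(SNP = "rs9", A1 = "G", A2 = "A")
  same_strand_flip <- symfactor:::new_sumstat(data.table::data.table(
    SNP = "rs9", A1 = "C", A2 = "T", Z = 2, N = 100))
  out <- harmonize_sumstats(same_strand_flip, ref)
  expect_equal(out$Z, 2)  # complement(C,T) = (G,A): aligned, no flip
  swapped_flip <- symfactor:::new_sumstat(data.table::data.table(
    SNP = "rs9", A1 = "T", A2 = "C", Z = 2, N = 100))
  out2 <- harmonize_sumstats(swapped_flip, ref)
  expect_equal(out2$Z, -2)  # complement(T,C) = (A,G): swapped, flip
  # irreconcilable alleles are dropped and counted
  bad <- symfactor:::new_sumstat(data.table::data.table(
    SNP = "rs9", A1 = "A", A2 = "C", Z = 2, N = 100))
  out3 <- harmonize_sumstats(bad, ref)
  expect_equal(nrow(out3), 0)
  expect_equal(attr(out3, "harmonize_report")$mismatched, 1L)
})

test_that("harmonization is involutive", {
  ref <- data.frame(SNP = paste0("rs", 1:4),
                    A1 = c("A", "A", "G", "T"), A2 = c("G", "C", "A", "C"))
  set.seed(2)
  obs <- symfactor:::new_sumstat(data.table::data.table(
    SNP = paste0("rs", 1:4), A1 = c("G", "A", "G", "T"),
    A2 = c("A", "C", "A", "C"), Z = stats::rnorm(4), N = 1000))
  once <- harmonize_sumstats(obs, ref)
  twice <- harmonize_sumstats(once, ref)
  for (col in names(once))
    expect_identical(twice[[col]], once[[col]], info = col)
  expect_equal(attr(twice, "harmonize_report")$sign_flipped, 0L)
})

test_that("effective sample size follows 4/(1/Ncase + 1/Ncontrol)", {
  expect_equal(effective_n(100, 100), 200)
  expect_equal(effective_n(100, 300), 300)
  expect_equal(effective_n(c(100, 150), c(300, 150)), c(300, 300))
  # meta-analysis N_eff is the sum over cohorts
  expect_equal(sum(effective_n(100, 100), effective_n(100, 300)), 500)
  expect_error(effective_n(0, 10))
})

test_that("inverse-variance meta-analysis matches closed forms", {
  t1 <- symfactor:::new_sumstat(data.table::data.table(
    SNP = "rs1", A1 = "A", A2 = "G", BETA = 0.1, SE = 0.1, N_EFF = 200))
  t2 <- symfactor:::new_sumstat(data.table::data.table(
    SNP = "rs1", A1 = "A", A2 = "G", BETA = 0.3, SE = 0.1, N_EFF = 300))
  m <- ivw_meta(list(t1, t2))
  expect_equal(m$BETA, 0.2)
  expect_equal(m$SE, 0.1 / sqrt(2), tolerance = 1e-10)
  expect_equal(m$N_EFF, 500)
  # single table: identity
  m1 <- ivw_meta(list(t1))
  expect_equal(m1$BETA, t1$BETA)
  expect_equal(m1$SE, t1$SE)
  # two identical studies: same beta, se / sqrt(2)
  m2 <- ivw_meta(list(t1, t1))
  expect_equal(m2$BETA, 0.1)
  expect_equal(m2$SE, 0.1 / sqrt(2))
})

test_that("meta-analysis is order-invariant and uses union semantics", {
  set.seed(3)
  mk <- function(snps) symfactor:::new_sumstat(data.table::data.table(
    SNP = snps, A1 = "A", A2 = "G", BETA = stats::rnorm(length(snps), 0, .1),
    SE = stats::runif(length(snps), .02, .1), N_EFF = 1000))
  a <- mk(paste0("rs", 1:6)); b <- mk(paste0("rs", 4:9))
  m_ab <- ivw_meta(list(a, b)); m_ba <- ivw_meta(list(b, a))
  m_ab <- m_ab[order(m_ab$SNP)]; m_ba <- m_ba[order(m_ba$SNP)]
  expect_equal(m_ab$BETA, m_ba$BETA)
  expect_equal(m_ab$SE, m_ba$SE)
  expect_setequal(m_ab$SNP, paste0("rs", 1:9))
  expect_equal(m_ab$N_COHORTS[m_ab$SNP == "rs5"], 2L)
  expect_equal(m_ab$N_COHORTS[m_ab$SNP == "rs1"], 1L)
  # disjoint variant sets warn but produce the union
  d1 <- mk(paste0("rs", 1:3)); d2 <- mk(paste0("rs", 11:13))
  expect_warning(md <- ivw_meta(list(d1, d2)), "union")
  expect_equal(nrow(md), 6)
})

test_that("QC attributes every dropped row to exactly one rule", {
  dt <- symfactor:::new_sumstat(data.table::data.table(
    SNP = paste0("rs", 1:6), A1 = "A", A2 = "G",
    BETA = 0.1, SE = 0.05,
    FREQ = c(0.5, 0.005, 0.5, 0.004, 0.5, 0.5),
    INFO = c(0.95, 0.5, 0.95, 0.95, 0.95, 0.95),
    N_EFF = c(10000, 10000, 1000, 10000, 10000, 10000)))
  out <- qc_sumstats(dt, qc_config())
  rep <- attr(out, "qc_report")
  expect_equal(nrow(out), 3)
  expect_equal(sum(rep$dropped), 3)  # rs2 info (first rule), rs3 n_eff, rs4 maf
  expect_equal(rep$dropped[rep$rule == "info"], 1L)
  expect_equal(rep$dropped[rep$rule == "maf"], 1L)
  expect_equal(rep$dropped[rep$rule == "n_eff"], 1L)
  expect_true(nrow(out) <= nrow(dt))
})
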