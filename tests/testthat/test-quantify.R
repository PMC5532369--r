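test_that("error-free reads place uniquely at their true origin", {
  ref <- build_reference(n_offtarget_cpgs = 30, target_gaps = 12,
                         topology = "circular", seed = 51)
  spec <- set_site_probability(ref$spec, ref$targets$c_forward_pos + 1L,
                               "-", 0.344)
  st <- sample_molecules(spec, 100, seed = 52)
  cv <- bisulfite_convert(st, ref$record, spec)
  rd <- sample_reads(cv, ref$record, read_length = 75, depth = 60,
                     error_rate = 0, seed = 53)
  pl <- align_bisulfite(rd, ref$record, max_mismatches = 0)
  tv <- parse_read_names(pl$name)
  expect_true(all(pl$status == "unique"))
  expect_true(all(pl$start == tv$start))
  expect_true(all(pl$strand == tv$strand))
  expect_true(all(pl$mismatches == 0))
  # reads from fully methylated molecules still align with 0 mismatches
  stm <- matrix(1L, 5, nrow(spec))
  cvm <- bisulfite_convert(stm, ref$record, spec)
  rdm <- sample_reads(cvm, ref$record, read_length = 75, depth = 10,
                      error_rate = 0, seed = 54)
  plm <- align_bisulfite(rdm, ref$record, max_mismatches = 0)
  expect_true(all(plm$mismatches == 0))
})

test_that("a reverse-complemented read is assigned to the bottom strand", {
  r <- seq_record(random_dna(120, seed = 55))
  # bottom-strand read: revcomp of forward window, then C->T on its own
  # strand by taking it from the converted bottom sequence
  spec <- data.frame(pos = integer(0), strand = character(),
                     prob = numeric(0), target = logical(0))
  cv <- bisulfite_convert(matrix(integer(0), 1, 0), r, spec)
  rd <- data.frame(name = "bot|bottom|31",
                   seq = substr(cv$bottom, 31, 70))
  pl <- align_bisulfite(rd, r, max_mismatches = 0)
  expect_equal(pl$strand, "bottom")
  expect_equal(pl$start, 31L)
})

test_that("methylation calling aggregates per cytosine with NA at zero coverage", {
  # 3 methylated + 7 unmethylated reads over one CpG on a random
  # (non-palindromic) background so placements are unambiguous
  ch <- strsplit(random_dna(60, seed = 56), "", fixed = TRUE)[[1]]
  ch <- plant_cpg(ch, 30)
  r <- seq_record(paste(ch, collapse = ""))
  reads <- data.frame(
    name = sprintf("mol%06d|top|11", 1:10),
    seq = vapply(1:10, function(i) {
      s <- substr(r$seq, 11, 50)
      pos_in_read <- 30 - 11 + 1
      substr(s, pos_in_read, pos_in_read) <- if (i <= 3) "C" else "T"
      s
    }, character(1)))
  pl <- align_bisulfite(reads, r, max_mismatches = 1)
  tab <- call_methylation(pl)
  site <- tab[tab$pos == 30 & tab$strand == "+", ]
  expect_equal(site$meth, 3)
  expect_equal(site$unmeth, 7)
  expect_equal(site$coverage, 10)
  expect_equal(site$fraction, 0.3)
  expect_equal(site$context, "CpG")
  # the uncovered reverse-strand C reports NA, never 0
  rev_site <- tab[tab$pos == 31 & tab$strand == "-", ]
  expect_equal(rev_site$coverage, 0)
  expect_true(is.na(rev_site$fraction))
})

test_that("a fully methylated simulation reports fraction 1 at every CpG", {
  ref <- build_reference(n_offtarget_cpgs = 15, target_gaps = 12,
                         topology = "circular", seed = 61)
  spec <- ref$spec
  spec$prob <- 1
  st <- sample_molecules(spec, 60, seed = 62)
  cv <- bisulfite_convert(st, ref$record, spec)
  rd <- sample_reads(cv, ref$record, read_length = 75, depth = 80,
                     error_rate = 0, seed = 63)
  tab <- call_methylation(align_bisulfite(rd, ref$record))
  cpg <- tab[tab$context == "CpG" & tab$coverage > 0, ]
  expect_true(all(cpg$fraction == 1))
  # non-CpG cytosines in a CpG-only simulation stay unmethylated
  cph <- tab[tab$context == "CpH" & tab$coverage > 0, ]
  expect_true(all(cph$fraction == 0))
})

test_that("the simulate-quantify round trip recovers specified probabilities", {
  ref <- build_reference(n_offtarget_cpgs = 40, target_gaps = 12,
                         topology = "circular", seed = 71)
  spec <- ref$spec
  spec <- set_site_probability(spec, ref$targets$c_forward_pos + 1L, "-",
                               0.344)
  spec <- set_site_probability(spec, ref$targets$c_forward_pos, "+", 0.15)
  st <- sample_molecules(spec, 4000, seed = 72)
  cv <- bisulfite_convert(st, ref$record, spec)
  rd <- sample_reads(cv, ref$record, read_length = 75, depth = 500,
                     error_rate = 0, seed = 73)
  tab <- call_methylation(align_bisulfite(rd, ref$record))
  key <- paste(tab$pos, tab$strand)
  idx <- match(paste(spec$pos, spec$strand), key)
  est <- tab$fraction[idx]
  cov <- tab$coverage[idx]
  expect_true(all(cov >= 100))
  se <- sqrt(pmax(spec$prob * (1 - spec$prob), 1e-6) / cov)
  mad <- mean(abs(est - spec$prob))
  expect_lte(mad, 2 * mean(se) + 1e-6)
  # every site individually within binomial noise (3.5 se + molecule term)
  se_full <- sqrt(pmax(spec$prob * (1 - spec$prob), 1e-6) *
                    (1 / 4000 + 1 / cov))
  expect_true(mean(abs(est - spec$prob) <= 3.5 * se_full + 1e-9) >= 0.95)
})

test_that("fold preference follows the target-over-median-off-target convention", {
  mk <- function(fracs, cov = 1000) {
    data.frame(pos = seq(10, by = 10, length.out = length(fracs)),
               strand = "+", context = "CpG",
               meth = round(fracs * cov), unmeth = cov - round(fracs * cov),
               coverage = cov, fraction = fracs)
  }
  tab <- mk(c(0.344, 0.005, 0.00593, 0.007))
  targets <- data.frame(pos = 10, strand = "+")
  expect_equal(fold_preference(tab, targets), 0.344 / 0.00593,
               tolerance = 0.1 / 58)
  # target equal to the median gives 1
  tab2 <- mk(c(0.01, 0.01, 0.01, 0.01))
  expect_equal(fold_preference(tab2, targets), 1)
  # an all-zero background falls back to the pseudo-floor
  tab3 <- mk(c(0.344, 0, 0, 0))
  f <- 1 / (2 * 3000)
  expect_equal(fold_preference(tab3, targets), 0.344 / f)
  expect_equal(fold_preference(tab3, targets, pseudo_floor = 0.01),
               0.344 / 0.01)
  # low-coverage sites are excluded from the median
  tab4 <- mk(c(0.344, 0.005, 0.00593, 0.007))
  tab4$coverage[2] <- 5
  expect_equal(fold_preference(tab4, targets),
               0.344 / median(c(0.00593, 0.007)))
})

test_that("profile correlation is squared Pearson and matches the textbook formula", {
  mk <- function(fracs, cov = 100) {
    data.frame(pos = seq_along(fracs) * 7, strand = "+", context = "CpG",
               meth = round(fracs * cov), unmeth = cov - round(fracs * cov),
               coverage = cov, fraction = fracs)
  }
  set.seed(81)
  x <- runif(200, 0, 0.3)
  a <- mk(x)
  expect_equal(compare_profiles(a, a), 1)
  b <- mk(0.1 + 2 * x)            # positive affine transform
  expect_equal(compare_profiles(a, b), 1)
  y <- runif(200, 0, 0.3)
  r2 <- compare_profiles(a, mk(y))
  expect_equal(r2, oracle_pearson(x, y)^2, tolerance = 1e-10)
  expect_lt(r2, 0.2)              # independent backgrounds barely correlate
  # zero variance is undefined, reported as missing
  flat <- mk(rep(0.05, 200))
  expect_warning(r2f <- compare_profiles(a, flat), "variance")
  expect_true(is.na(r2f))
  expect_error(compare_profiles(a[1:2, ], a[1:2, ]), "at least 3")
})

test_that("co-methylation joins per-molecule calls across sites", {
  # two CpGs on a short random reference; moderate depth over few molecules
  ch <- strsplit(random_dna(150, seed = 90), "", fixed = TRUE)[[1]]
  ch <- plant_cpg(ch, 40)
  ch <- plant_cpg(ch, 90)
  r <- seq_record(paste(ch, collapse = ""), topology = "circular")
  spec <- data.frame(pos = c(40, 41, 90, 91),
                     strand = c("+", "-", "+", "-"),
                     prob = c(0.6, 0, 0.4, 0), target = FALSE)
  st <- sample_molecules(spec, 200, seed = 91)
  cv <- bisulfite_convert(st, r, spec)
  rd <- sample_reads(cv, r, read_length = 75, depth = 1200,
                     error_rate = 0, seed = 92)
  pl <- align_bisulfite(rd, r)
  pos <- data.frame(pos = c(40, 90), strand = "+")
  cm <- comethylation_matrix(pl, pos)
  # diagonal equals the per-molecule marginals of the truth states
  truth1 <- mean(st[, 1]); truth2 <- mean(st[, 3])
  expect_equal(cm[1, 1], truth1, tolerance = 0.05)
  expect_equal(cm[2, 2], truth2, tolerance = 0.05)
  # joint tracks the realized same-molecule co-methylation, which for
  # independent sites sits near the product of marginals
  realized_joint <- mean(st[, 1] == 1 & st[, 3] == 1)
  expect_lt(abs(cm[1, 2] - realized_joint), 0.05)
  expect_lt(abs(cm[1, 2] - truth1 * truth2), 0.1)
  expect_equal(cm[1, 2], cm[2, 1])
  # fully methylated molecules give an all-ones matrix
  stm <- matrix(1L, 30, 4)
  cvm <- bisulfite_convert(stm, r, spec)
  rdm <- sample_reads(cvm, r, read_length = 75, depth = 600,
                      error_rate = 0, seed = 93)
  cmm <- comethylation_matrix(align_bisulfite(rdm, r), pos)
  expect_true(all(cmm == 1))
})

test_that("methylation tables export as TSV and strand-split bedGraph", {
  ref <- build_reference(n_offtarget_cpgs = 10, target_gaps = 12,
                         topology = "circular", seed = 95)
  st <- sample_molecules(ref$spec, 20, seed = 96)
  cv <- bisulfite_convert(st, ref$record, ref$spec)
  rd <- sample_reads(cv, ref$record, read_length = 75, depth = 30,
                     error_rate = 0, seed = 97)
  tab <- call_methylation(align_bisulfite(rd, ref$record))
  tf <- tempfile(fileext = ".tsv")
  write_methylation_table(tab, tf)
  expect_equal(nrow(read.delim(tf)), nrow(tab))
  pre <- tempfile()
  write_bedgraph(tab, ref$record, pre)
  plus <- read.delim(paste0(pre, ".plus.bedGraph"), header = FALSE)
  expect_true(all(plus$V3 - plus$V2 == 1))
  expect_true(all(plus$V4 >= 0 & plus$V4 <= 1))
})
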