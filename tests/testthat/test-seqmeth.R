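test_that("find_cpg_sites matches direct scans and rejects bad input", {
  expect_identical(find_cpg_sites("ACGCGT"), c(1L, 3L))
  expect_identical(find_cpg_sites("ATTGGA"), integer(0))
  expect_identical(find_cpg_sites("acgcgt"), c(1L, 3L))  # case-insensitive
  expect_identical(find_cpg_sites("CNGCG"), 3L)          # N breaks a site

  set.seed(42)
  seq <- random_dna(1000)
  # independent oracle: linear scan over dinucleotides
  chars <- strsplit(seq, "")[[1]]
  oracle <- which(chars[-length(chars)] == "C" & chars[-1] == "G") - 1L
  expect_identical(find_cpg_sites(seq), as.integer(oracle))

  expect_error(find_cpg_sites("ACGXGT"), "position 3")
})

test_that("bisulfite conversion follows the chemistry on both strands", {
  expect_identical(bisulfite_convert("TACGTC", 2), "TACGTT")
  expect_identical(bisulfite_convert("TACGTC", integer(0)), "TATGTT")
  # bottom strand of ACGT is ACGT; its unmethylated CpG-C converts
  expect_identical(bisulfite_convert("ACGT", integer(0), strand = "-"),
                   "ATGT")
  # methylated CpG protects the bottom-strand C as well
  expect_identical(bisulfite_convert("ACGT", 1, strand = "-"), "ACGT")
  # N passes through; position not a CpG is an error
  expect_identical(bisulfite_convert("ANCGT", 2), "ANCGT")
  expect_error(bisulfite_convert("TACGTC", 0), "not CpG")
  expect_error(bisulfite_convert("TACGTC", 3), "not CpG")
})

test_that("conversion totality: no C survives except methylated CpGs", {
  set.seed(7)
  for (i in 1:20) {
    seq <- random_dna(300)
    cpgs <- find_cpg_sites(seq)
    meth <- cpgs[rbinom(length(cpgs), 1, 0.5) == 1]
    conv <- bisulfite_convert(seq, meth)
    c_pos <- find_cpg_sites(conv)  # CG survivors
    all_c <- which(strsplit(conv, "")[[1]] == "C") - 1L
    expect_identical(sort(all_c), sort(meth))
    expect_identical(sort(c_pos), sort(meth))
    # idempotence surrogate: a fully converted unmethylated sequence is fixed
    unm <- bisulfite_convert(seq, integer(0))
    expect_identical(bisulfite_convert(unm, integer(0)), unm)
  }
})

test_that("MSP templates differ at exactly the CpG-C positions", {
  tpl <- make_msp_templates("TACGTC")
  expect_identical(tpl$plus_methylated, "TACGTT")
  expect_identical(tpl$plus_unmethylated, "TATGTT")

  no_cpg <- "TTAGGATTAG"
  tpl0 <- make_msp_templates(no_cpg)
  expect_identical(tpl0$plus_methylated, tpl0$plus_unmethylated)
  expect_identical(tpl0$minus_methylated, tpl0$minus_unmethylated)

  set.seed(11)
  for (i in 1:10) {
    seq <- random_dna(400)
    n_cpg <- length(find_cpg_sites(seq))
    tpl <- make_msp_templates(seq)
    diff_plus <- which(strsplit(tpl$plus_methylated, "")[[1]] !=
                         strsplit(tpl$plus_unmethylated, "")[[1]])
    expect_length(diff_plus, n_cpg)
    diff_minus <- which(strsplit(tpl$minus_methylated, "")[[1]] !=
                          strsplit(tpl$minus_unmethylated, "")[[1]])
    expect_length(diff_minus, n_cpg)
  }
})

test_that("a 34-CpG amplicon yields templates differing at 34 positions", {
  cfg <- small_config(seed = 5)
  locus <- simulate_locus(cfg)
  sites <- head(locus$cpg_sites_cgi, 34)
  amp <- substr(locus$seq, sites[1] + 1, sites[34] + 2)
  expect_identical(length(find_cpg_sites(amp)), 34L)
  tpl <- make_msp_templates(amp)
  diffs <- sum(strsplit(tpl$plus_methylated, "")[[1]] !=
                 strsplit(tpl$plus_unmethylated, "")[[1]])
  expect_identical(diffs, 34L)
})

test_that("primer_matches is exact-match in both orientations", {
  tpl <- "TTAGGTTTAGGATTTAGGGT"
  expect_identical(primer_matches("TTAGGTTTAG", tpl), 0L)
  expect_identical(primer_matches(bisulfite_convert("TTAGGTTTAG",
                                                    integer(0)), tpl), 0L)
  # M-specific primer fails on the unmethylated template (one CpG apart)
  seq <- "TTACGTTAGGATTAGGTT"
  tpls <- make_msp_templates(seq)
  m_primer <- substr(tpls$plus_methylated, 1, 12)
  expect_true(length(primer_matches(m_primer, tpls$plus_methylated)) > 0)
  expect_identical(primer_matches(m_primer, tpls$plus_unmethylated),
                   integer(0))
  expect_error(primer_matches("ACGTACGT", tpl), ">= 10")

  # brute-force sliding-window oracle on random primer/template pairs
  set.seed(99)
  rc <- function(s) as.character(
    Biostrings::reverseComplement(Biostrings::DNAString(s)))
  for (i in 1:100) {
    template <- random_dna(60)
    primer <- if (i %% 2 == 0) random_dna(10) else {
      at <- sample(50, 1)
      substr(template, at, at + 9)  # guaranteed hit
    }
    naive <- integer(0)
    for (p in c(primer, rc(primer))) {
      for (start in seq_len(nchar(template) - nchar(p) + 1)) {
        if (substr(template, start, start + nchar(p) - 1) == p)
          naive <- c(naive, start - 1L)
      }
    }
    expect_identical(primer_matches(primer, template),
                     sort(unique(naive)))
  }
})

test_that("trace quantification and classification follow the ratio bands", {
  expect_equal(quantify_trace(900, 100), 0.9)
  expect_equal(quantify_trace(50, 50), 0.5)
  expect_equal(quantify_trace(0, 120), 0)
  expect_error(quantify_trace(0, 0), "undefined")
  expect_error(quantify_trace(-1, 5), "non-negative")

  expect_identical(classify_bs_ratio(0.15), "unmethylated")
  expect_identical(classify_bs_ratio(0.5), "partial")
  expect_identical(classify_bs_ratio(0.9), "methylated")
  # boundaries per the printed two-decimal bands
  expect_identical(classify_bs_ratio(c(0, 0.2, 0.21, 0.8, 0.81, 1)),
                   c("unmethylated", "unmethylated", "partial", "partial",
                     "methylated", "methylated"))
  expect_error(classify_bs_ratio(1.2), "0, 1")

  # total monotone step function over [0, 1]
  grid <- seq(0, 1, by = 0.001)
  calls <- classify_bs_ratio(grid)
  lev <- match(calls, c("unmethylated", "partial", "methylated"))
  expect_true(all(diff(lev) >= 0))
  expect_false(anyNA(lev))
})

test_that("trace tables recall the simulated methylation fraction", {
  cfg <- small_config(seed = 3, trace_depth = 500, trace_n_sites = 34)
  locus <- simulate_locus(cfg)
  # 100 sites at depth 500: mean ratio within 0.05 of the true fraction
  cfg2 <- small_config(seed = 3, trace_depth = 500, trace_n_sites = 100,
                       cgi_cpg_count = 110)
  locus2 <- simulate_locus(cfg2)
  fr <- c(x_1 = 0.5, x_2 = 0.15, x_3 = 0.9)
  traces <- simulate_traces(cfg2, fr, locus2)
  expect_identical(nrow(traces$x_1), 100L)
  expect_lt(abs(mean(call_traces(traces$x_1)$ratio) - 0.5), 0.05)
  expect_lt(abs(mean(call_traces(traces$x_2)$ratio) - 0.15), 0.05)
  expect_lt(abs(mean(call_traces(traces$x_3)$ratio) - 0.9), 0.05)

  # degenerate fractions give uniform calls
  tr0 <- simulate_traces(cfg, c(a = 0.01), locus)$a
  tr0$c_height <- 0 * tr0$c_height  # force pure-T traces: fraction 0
  expect_true(all(call_traces(tr0)$call == "unmethylated"))
  tr1 <- simulate_traces(cfg, c(a = 0.99), locus)$a
  tr1$t_height <- 0 * tr1$t_height  # pure-C traces: fraction 1
  expect_true(all(call_traces(tr1)$call == "methylated"))

  # zero-total site becomes a no-call, not a zero
  tr <- data.frame(site = c(1, 5), c_height = c(0, 10), t_height = c(0, 30))
  expect_message(out <- call_traces(tr), "no-call")
  expect_true(is.na(out$ratio[1]) && out$call[1] == "no-call")
  expect_equal(out$ratio[2], 0.25)
})

test_that("MSP calls are determined by the two band booleans", {
  expect_identical(call_msp(TRUE, FALSE)$status, "methylated")
  expect_identical(call_msp(FALSE, TRUE)$status, "unmethylated")
  expect_identical(call_msp(TRUE, TRUE)$status, "hemimethylated")
  expect_identical(call_msp(FALSE, FALSE)$status, "failed")
  expect_identical(call_msp(c(TRUE, FALSE), c(TRUE, FALSE)),
                   c("hemimethylated", "failed"))
})

test_that("interval display convention round-trips losslessly", {
  gi <- genomic_interval("chr8", 41654876, 41655984)
  expect_identical(format_interval(gi), "chr8:41654877-41655984")
  back <- parse_interval(format_interval(gi))
  expect_equal(back$start, gi$start)
  expect_equal(back$end, gi$end)
  expect_identical(interval_width(gi), 1108L)
  # browser text with thousands separators parses too
  with_commas <- parse_interval("chr8:41654877-41,655,984")
  expect_equal(with_commas$end, 41655984)
  expect_error(genomic_interval("chr1", 10, 10), "start")
  expect_error(genomic_interval("chr1", 0, 5, strand = "x"), "strand")
  expect_identical(in_interval(c(9, 10, 14, 15), genomic_interval("c", 10, 15)),
                   c(FALSE, TRUE, TRUE, FALSE))
})
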