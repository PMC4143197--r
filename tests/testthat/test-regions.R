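test_that("read_genome parses, normalises case and rejects duplicates", {
  fa <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">chr1 desc", paste(rep("acgta", 10), collapse = ""),
               ">chr2", paste(rep("ACGNAC", 5), collapse = "")), fa)
  g <- read_genome(fa)
  expect_named(g, c("chr1", "chr2"))
  expect_equal(nchar(g), c(chr1 = 50L, chr2 = 30L))
  expect_equal(substr(g[["chr1"]], 1, 4), "ACGT")
  expect_true(grepl("N", g[["chr2"]]))

  dup <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "TTTT"), dup)
  expect_error(read_genome(dup), "duplicate")
})

test_that("select_primary_tss keeps the most upstream TSS per strand", {
  tss <- data.frame(
    gene_id = c("gp", "gp", "gp", "gm", "gm", "gm", "single"),
    chrom = "chr1",
    strand = c("+", "+", "+", "-", "-", "-", "+"),
    tss = c(1200L, 980L, 1500L, 1200L, 980L, 1500L, 77L))
  out <- select_primary_tss(tss)
  expect_equal(nrow(out), 3L)
  expect_equal(out$tss[out$gene_id == "gp"], 980L)
  expect_equal(out$tss[out$gene_id == "gm"], 1500L)
  expect_equal(out$tss[out$gene_id == "single"], 77L)

  bad <- data.frame(gene_id = "g", chrom = "chr1", strand = c("+", "-"),
                    tss = c(1L, 2L))
  expect_error(select_primary_tss(bad), "mixed strands")
})

test_that("extract_regions obeys the coordinate convention on both strands", {
  set.seed(9)
  chrom <- paste(sample(c("A", "C", "G", "T"), 20000, TRUE), collapse = "")
  genome <- c(chr1 = chrom)
  tss <- data.frame(gene_id = c("p", "m"), chrom = "chr1",
                    strand = c("+", "-"), tss = c(10000L, 10000L))
  regs <- extract_regions(genome, tss, upstream = 1500, downstream = 500)
  expect_equal(nchar(regs$sequence), c(2000L, 2000L))
  # plus strand: genomic [8500, 10500) -> 1-based chars 8501..10500
  expect_equal(regs$sequence[1], substr(chrom, 8501, 10500))
  # the TSS base sits at offset tss_offset
  expect_equal(substr(regs$sequence[1], 1501, 1501), substr(chrom, 10001, 10001))
  # minus strand: brute-force check base by base against the raw chromosome:
  # region offset i (0-based) must be the complement of genomic base
  # tss + upstream - i
  sm <- strsplit(regs$sequence[2], "")[[1]]
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  for (i in c(0L, 1L, 777L, 1500L, 1999L)) {
    gbase <- substr(chrom, 10000 + 1500 - i + 1, 10000 + 1500 - i + 1)
    expect_identical(sm[i + 1], unname(comp[gbase]))
  }
})

test_that("regions near chromosome ends follow the boundary policy", {
  genome <- c(c1 = strrep("ACGT", 500))   # 2000 bp
  tss <- data.frame(gene_id = "g", chrom = "c1", strand = "+", tss = 800L)
  regs <- extract_regions(genome, tss, upstream = 1500, downstream = 500)
  expect_equal(nchar(regs$sequence), 2000L)
  expect_equal(substr(regs$sequence, 1, 700), strrep("N", 700))
  expect_warning(
    skipped <- extract_regions(genome, tss, 1500, 500, boundary = "skip"),
    "skipped")
  expect_equal(nrow(skipped), 0L)
  expect_error(
    extract_regions(genome, data.frame(gene_id = "g", chrom = "nope",
                                       strand = "+", tss = 10L), 100, 50),
    "unknown chromosome")
})

test_that("extraction round-trips through the mirrored chromosome", {
  # extracting on + at coordinate t, and on - at the mirrored coordinate of
  # the reverse-complemented chromosome, must give identical sequences
  set.seed(11)
  chrom <- paste(sample(c("A", "C", "G", "T"), 6000, TRUE), collapse = "")
  L <- nchar(chrom)
  t_plus <- 3000L
  fwd <- extract_regions(c(c = chrom),
                         data.frame(gene_id = "g", chrom = "c", strand = "+",
                                    tss = t_plus), 1000, 400)
  mir <- extract_regions(c(c = rc(chrom)),
                         data.frame(gene_id = "g", chrom = "c", strand = "-",
                                    tss = L - 1L - t_plus), 1000, 400)
  expect_identical(fwd$sequence, mir$sequence)
})

test_that("gene sets derive from tissue means and Z-scores", {
  set.seed(3)
  n <- 100
  expr <- matrix(rnorm(n * 8, mean = 5), n, 8,
                 dimnames = list(sprintf("g%03d", 1:n),
                                 c(paste0("ant", 1:3), paste0("body", 1:5))))
  planted <- sprintf("g%03d", 1:10)
  expr[planted, 1:3] <- expr[planted, 1:3] + 50
  sets <- select_gene_sets(expr, paste0("ant", 1:3), top_n = 10)
  expect_setequal(sets$positive, planted)
  expect_true(all(sets$z[sets$negative] < -1))
  expect_length(intersect(sets$positive, sets$negative), 0L)

  # centered and 2-SD-below constructions behave as the definition demands
  e2 <- rbind(flat = rep(c(4, 4, 6, 6), each = 2))
  e2 <- rbind(e2, low = c(1, 1, 5, 5, 5, 5, 5, 5))
  colnames(e2) <- c("t1", "t2", paste0("o", 1:6))
  s2 <- select_gene_sets(e2, c("t1", "t2"), top_n = 1)
  z <- s2$z
  expect_lt(z[["low"]], -1)
  expect_true("low" %in% s2$negative)

  ezv <- matrix(2, 2, 4, dimnames = list(c("a", "b"), c("t1", "o1", "o2", "o3")))
  expect_warning(select_gene_sets(ezv, "t1", top_n = 1), "zero-variance")
})
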