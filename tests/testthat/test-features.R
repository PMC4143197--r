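hit <- function(motif_id, start, strand) {
  data.frame(motif_id = motif_id, start = start, strand = strand,
             stringsAsFactors = FALSE)
}

test_that("single hits yield TSS-distance and orientation features", {
  # a hit 150 bp upstream on the minus strand: '~100-200 bp from the TSS on
  # the minus strand', plus its either-strand variant and its orientation
  f <- features_of_region(hit("DME-5", -150L, "-"))
  expect_setequal(f, c("tss|DME-5|u1|-", "tss|DME-5|u1|.", "orient|DME-5|-"))
  # downstream hit at the TSS base itself falls in bin d0
  f2 <- features_of_region(hit("M", 0L, "+"))
  expect_true("tss|M|d0|+" %in% f2)
  expect_equal(features_of_region(hit(character(0), integer(0),
                                      character(0))),
               character(0))
})

test_that("hit pairs yield unsigned spacing bins with strand constraints", {
  # two same-motif hits 60 bp apart, both plus: '~0-100 bp from DME-3 on the
  # plus strand'
  h <- rbind(hit("DME-3", -400L, "+"), hit("DME-3", -340L, "+"))
  f <- features_of_region(h)
  expect_true("pair|DME-3,DME-3|0|++" %in% f)
  expect_true("pair|DME-3,DME-3|0|.." %in% f)
  # canonicalisation: member order never depends on input order
  h2 <- rbind(hit("B", -100L, "-"), hit("A", -400L, "+"))
  h3 <- rbind(hit("A", -400L, "+"), hit("B", -100L, "-"))
  expect_setequal(features_of_region(h2), features_of_region(h3))
  expect_true("pair|A,B|3|+-" %in% features_of_region(h2))
})

test_that("order features enumerate pairs and triples but never quadruples", {
  h <- rbind(hit("A", -900L, "+"), hit("B", -500L, "-"),
             hit("C", -200L, "+"), hit("D", 100L, "+"))
  f <- features_of_region(h, max_order = 3)
  ord <- grep("^order\\|", f, value = TRUE)
  # C(4,2) pairs + C(4,3) triples, all motifs distinct -> 10 sequences
  expect_length(ord, 10L)
  expect_true(all(feature_arity(ord) <= 3))
  expect_true("order|A>B>C" %in% ord)
  expect_false(any(grepl("A>B>C>D", ord)))
  # order ignores orientation: flipping strands leaves order features alone
  h_flipped <- transform(h, strand = "-")
  expect_setequal(grep("^order", features_of_region(h_flipped), value = TRUE),
                  ord)
})

test_that("shifting all hits by one window shifts only TSS bins", {
  h <- rbind(hit("A", -450L, "+"), hit("B", -220L, "-"))
  f0 <- features_of_region(h)
  h$start <- h$start + 100L
  f1 <- features_of_region(h)
  drop_tss <- function(f) grep("^tss", f, value = TRUE, invert = TRUE)
  expect_setequal(drop_tss(f0), drop_tss(f1))
  expect_true("tss|A|u4|+" %in% f0 && "tss|A|u3|+" %in% f1)
  expect_true("tss|B|u2|-" %in% f0 && "tss|B|u1|-" %in% f1)
})

test_that("strand-specific features always imply their either-strand variant", {
  set.seed(5)
  for (i in 1:20) {
    n <- sample(1:6, 1)
    h <- hit(sample(c("A", "B", "C"), n, TRUE),
             sample(-1500:499, n), sample(c("+", "-"), n, TRUE))
    f <- features_of_region(h)
    spec <- grep("^(tss|pair)\\|.*\\|[+-]{1,2}$", f, value = TRUE)
    gen <- c(sub("\\|[+-]$", "|.", spec), sub("\\|[+-]{2}$", "|..", spec))
    gen <- gen[grepl("\\|\\.{1,2}$", gen)]
    expect_true(all(gen %in% f))
  }
})

test_that("the library is the deduplicated union over positive regions", {
  h1 <- cbind(gene_id = "r1", hit("A", -150L, "+"))
  h2 <- cbind(gene_id = "r2", hit("A", -150L, "+"))
  lib1 <- build_feature_library(h1, "r1")
  lib2 <- build_feature_library(rbind(h1, h2), c("r1", "r2"))
  expect_identical(lib1, lib2)
  expect_setequal(lib1, c("tss|A|u1|+", "tss|A|u1|.", "orient|A|+"))
})

test_that("binarize fills presence and rejects duplicate regions", {
  hits <- rbind(cbind(gene_id = "r1", hit("A", -150L, "+")),
                cbind(gene_id = "r2", hit("A", -950L, "-")))
  lib <- build_feature_library(hits, c("r1", "r2"))
  fm <- binarize(lib, hits, c("r1", "r2", "r3"), c(1L, 0L, 0L))
  expect_equal(dim(fm$values), c(3L, length(lib)))
  expect_equal(fm$values["r1", "tss|A|u1|+"], 1L)
  expect_equal(fm$values["r2", "tss|A|u1|+"], 0L)
  expect_equal(unname(fm$values["r3", ]), rep(0L, length(lib)))  # no hits
  expect_error(binarize(lib, hits, c("r1", "r1"), c(1, 0)), "duplicated")
})

test_that("uniform random hits occupy TSS bins at the analytic rate", {
  # one hit placed uniformly over [-1500, 500): each either-strand 100-bp
  # upstream bin is occupied with probability 100/2000
  set.seed(77)
  n <- 4000
  starts <- sample(-1500:499, n, replace = TRUE)
  target <- "tss|M|u3|."
  occ <- vapply(starts, function(s)
    target %in% features_of_region(hit("M", s, "+")), logical(1))
  p <- 100 / 2000
  se <- sqrt(p * (1 - p) / n)
  expect_lt(abs(mean(occ) - p), 3 * se)
})
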