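mk_reads <- function(...) {
  rows <- list(...)
  do.call(rbind, lapply(rows, function(r)
    data.frame(seq_id = r[[1]], start = r[[2]], end = r[[3]], strand = r[[4]],
               stringsAsFactors = FALSE)))
}

test_that("read counting is strand-aware and per-locus independent", {
  loci <- locus_table(c("a", "b"), "chr1", c(100L, 200L), c(199L, 299L), "+")
  reads <- list(
    lib1 = mk_reads(list("chr1", 120L, 140L, "+"),    # inside a
                    list("chr1", 150L, 170L, "-"),    # opposite strand
                    list("chr1", 190L, 210L, "+")),   # spans a and b
    lib2 = mk_reads(list("chr1", 250L, 270L, "+")))
  ev <- count_reads(loci, reads)
  expect_identical(ev$lib1, c(2L, 1L))
  expect_identical(ev$lib2, c(0L, 1L))
  expect_identical(ev$total_reads, c(2L, 2L))
  ev2 <- count_reads(loci, reads, stranded = FALSE)
  expect_identical(ev2$lib1, c(3L, 1L))
  expect_warning(count_reads(loci, list(lib1 = reads$lib1,
                                        empty = reads$lib1[0, ])),
                 "zero reads")
})

test_that("counting equals a brute-force all-pairs overlap check", {
  set.seed(19)
  for (k in 1:20) {
    n_loci <- sample(3:20, 1)
    start <- sample.int(500, n_loci)
    loci <- locus_table(sprintf("L%02d", seq_len(n_loci)),
                        sample(c("c1", "c2"), n_loci, TRUE),
                        start, start + sample(20:80, n_loci, TRUE),
                        sample(c("+", "-"), n_loci, TRUE))
    n_reads <- sample(10:200, 1)
    rs <- sample.int(600, n_reads, replace = TRUE)
    reads <- list(lib = data.frame(
      seq_id = sample(c("c1", "c2"), n_reads, TRUE), start = rs,
      end = rs + sample(18:25, n_reads, TRUE) - 1L,
      strand = sample(c("+", "-"), n_reads, TRUE), stringsAsFactors = FALSE))
    ev <- count_reads(loci, reads)
    bf <- vapply(seq_len(n_loci), function(i)
      sum(vapply(seq_len(n_reads), function(j)
        bf_overlap(loci[i, ], reads$lib[j, ]) > 0L, NA)), 1L)
    expect_identical(ev$lib, bf)
  }
})

test_that("expression flags implement >=2 studies and strictly >10 reads", {
  ev <- data.frame(id = c("a", "b", "c", "d"),
                   lib1 = c(2L, 50L, 5L, 6L),
                   lib2 = c(2L, 0L, 5L, 5L),
                   lib3 = c(0L, 0L, 0L, 0L),
                   total_reads = c(4L, 50L, 10L, 11L),
                   n_libraries_with_reads = c(2L, 1L, 2L, 2L),
                   stringsAsFactors = FALSE)
  studies <- c(lib1 = "A", lib2 = "B", lib3 = "C")
  fl <- flag_expression(ev, studies)
  expect_identical(fl$expressed, c(TRUE, FALSE, TRUE, TRUE))
  expect_identical(fl$high_support, c(FALSE, TRUE, FALSE, TRUE))
  expect_identical(fl$expressed_or_high_support, c(TRUE, TRUE, TRUE, TRUE))
  # two libraries of the same study are one study
  same <- flag_expression(ev, c(lib1 = "A", lib2 = "A", lib3 = "B"))
  expect_identical(same$expressed[1], FALSE)
  expect_error(flag_expression(ev, c(lib1 = "A")), "unassigned")
})

test_that("flags are monotone when reads are added", {
  set.seed(23)
  studies <- c(lib1 = "A", lib2 = "B", lib3 = "C")
  for (k in 1:50) {
    counts <- matrix(rpois(3, 4), nrow = 1)
    ev <- data.frame(id = "x", lib1 = counts[1], lib2 = counts[2],
                     lib3 = counts[3], total_reads = sum(counts))
    more <- ev
    j <- sample(2:4, 1)
    more[[j]] <- more[[j]] + sample(1:20, 1)
    more$total_reads <- sum(unlist(more[2:4]))
    f1 <- flag_expression(ev, studies)
    f2 <- flag_expression(more, studies)
    expect_true(f2$expressed >= f1$expressed)
    expect_true(f2$high_support >= f1$high_support)
  }
})

test_that("count matrices export and round-trip through read_counts", {
  loci <- locus_table(c("a", "b", "c"), "chr1",
                      c(100L, 300L, 500L), c(180L, 380L, 580L), "+")
  reads <- list(lib1 = mk_reads(list("chr1", 110L, 130L, "+")),
                lib2 = mk_reads(list("chr1", 310L, 330L, "+"),
                                list("chr1", 320L, 340L, "+")),
                lib3 = mk_reads(list("chr1", 510L, 530L, "+")))
  ev <- count_reads(loci, reads)
  path <- withr::local_tempfile(fileext = ".tsv")
  export_count_matrix(ev, path)
  back <- read_counts(path)
  expect_identical(back$id, ev$id)
  expect_identical(back$lib2, ev$lib2)
  groups <- c(lib1 = "control", lib2 = "drought", lib3 = "drought")
  contrast <- build_contrast(back, groups)
  expect_identical(contrast$group, c("control", "drought", "drought"))
  expect_error(build_contrast(back, c(groups, lib9 = "x")), "unknown library")
})
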