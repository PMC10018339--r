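test_that("3' quality trimming follows the running-partial-sum rule", {
  r <- nuc_read("ACGTT", c(40L, 40L, 40L, 2L, 2L))
  tr <- quality_trim_3prime(r, 30L)
  expect_identical(tr$seq, "ACG")
  expect_identical(tr$qual, c(40L, 40L, 40L))
  # untouched when everything clears the cutoff
  hi <- nuc_read("ACGTACGT", 40L)
  expect_identical(quality_trim_3prime(hi, 30L), hi)
  # fully trimmed
  lo <- quality_trim_3prime(nuc_read("ACGT", 2L), 30L)
  expect_identical(lo$seq, "")
  # a high-quality base after a dip is kept if the partial sum recovers:
  # cut happens at the global minimum of the 3' partial sums
  mix <- nuc_read("ACGTACGTAC",
                  c(40L, 40L, 40L, 20L, 40L, 40L, 40L, 2L, 2L, 2L))
  tmix <- quality_trim_3prime(mix, 30L)
  expect_identical(tmix$seq, "ACGTACG")
})

test_that("merge_pair agrees with exhaustive overlap enumeration", {
  set.seed(101)
  for (case in 1:60) {
    n1 <- sample(30:80, 1)
    ov <- sample(5:min(40, n1), 1)
    ext <- sample(0:30, 1)
    tmpl <- random_dna(n1 + ext)
    r1 <- nuc_read(substr(tmpl, 1, n1), sample(30:40, n1, TRUE))
    r2raw <- substr(tmpl, n1 - ov + 1, n1 + ext)
    # sprinkle 0-4 mismatches into read 2
    r2c <- chars(r2raw)
    nmm <- sample(0:4, 1)
    if (nmm > 0) {
      idx <- sample(length(r2c), min(nmm, length(r2c)))
      r2c[idx] <- vapply(r2c[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    r2 <- nuc_read(rc(paste(r2c, collapse = "")),
                   sample(30:40, length(r2c), TRUE))
    got <- merge_pair(r1, r2, min_overlap = 20L, max_diffs = 2L)
    want <- merge_oracle(r1, r2, min_overlap = 20L, max_diffs = 2L)
    expect_identical(got$merged, want$merged, label = paste("case", case))
    if (got$merged) {
      expect_identical(got$seq, want$seq)
      expect_identical(got$qual, want$qual)
      expect_identical(got$overlap_len, want$overlap_len)
      expect_identical(got$n_diffs, want$n_diffs)
    } else {
      expect_identical(got$reason, want$reason)
    }
  }
})

test_that("merge thresholds are sharp at 20 nt overlap and 2 diffs", {
  tmpl <- random_dna(100)
  mk <- function(ov, nmm) {
    r1 <- nuc_read(substr(tmpl, 1, 60), 40L)
    r2c <- chars(substr(tmpl, 61 - ov, 100))
    if (nmm > 0) {
      idx <- seq(2, by = 3, length.out = nmm)  # inside the overlap
      r2c[idx] <- vapply(r2c[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    list(r1 = r1, r2 = nuc_read(rc(paste(r2c, collapse = "")), 35L))
  }
  set.seed(7)
  p20 <- mk(20, 0)
  expect_true(merge_pair(p20$r1, p20$r2)$merged)
  expect_identical(merge_pair(p20$r1, p20$r2)$overlap_len, 20L)
  p19 <- mk(19, 0)
  m19 <- merge_pair(p19$r1, p19$r2)
  expect_false(m19$merged)
  expect_identical(m19$reason, "too_short_overlap")
  p2 <- mk(25, 2)
  expect_true(merge_pair(p2$r1, p2$r2)$merged)
  p3 <- mk(25, 3)
  m3 <- merge_pair(p3$r1, p3$r2)
  expect_false(m3$merged)
})

test_that("merged length and overlap arithmetic", {
  tmpl <- random_dna(90)
  r1 <- nuc_read(substr(tmpl, 1, 60), 40L)
  r2 <- nuc_read(rc(substr(tmpl, 31, 90)), 40L)
  m <- merge_pair(r1, r2)
  expect_true(m$merged)
  expect_identical(m$overlap_len, 30L)
  expect_identical(m$n_diffs, 0L)
  expect_identical(nchar(m$seq), 90L)
  expect_identical(m$seq, tmpl)
})

test_that("consensus takes the higher-quality base; ties become N", {
  r1 <- nuc_read(paste(rep("A", 30), collapse = ""), 40L)
  # rc gives 30 T's back as A's complement; build r2 so its rc has one C
  rc2 <- paste0(paste(rep("A", 14), collapse = ""), "C",
                paste(rep("A", 15), collapse = ""))
  q2 <- rep(40L, 30L)
  r2_hi <- nuc_read(rc(rc2), rev(ifelse(seq_len(30) == 15, 41L, 40L)))
  m_hi <- merge_pair(r1, r2_hi, min_overlap = 20L, max_diffs = 2L)
  expect_identical(substr(m_hi$seq, 15, 15), "C")
  r2_tie <- nuc_read(rc(rc2), 40L)
  m_tie <- merge_pair(r1, r2_tie, min_overlap = 20L, max_diffs = 2L)
  expect_identical(substr(m_tie$seq, 15, 15), "N")
  expect_identical(m_tie$qual[15], 2L)
})

test_that("primer trimming removes terminal matches within the error budget", {
  p5 <- "ACGTACGTACGTACGTACGT"  # 20 nt
  p3 <- "TTGCATTGCATTGCATTGCA"
  core <- random_dna(100)
  seq <- paste0(p5, core, p3)
  expect_identical(trim_primers(seq, p5, p3, 0.1), core)
  # one mismatch in a 20-nt primer is within rate 0.1
  p5mm <- paste0("T", substr(p5, 2, 20))
  expect_identical(trim_primers(paste0(p5mm, core), p5, NULL, 0.1), core)
  # three mismatches are not
  p5mm3 <- paste0("TTT", substr(p5, 4, 20))
  expect_identical(trim_primers(paste0(p5mm3, core), p5, NULL, 0.1),
                   paste0(p5mm3, core))
  # absent primer leaves the sequence unchanged
  expect_identical(trim_primers(core, p5, p3, 0.1), core)
})

test_that("length filter bounds are inclusive", {
  expect_true(length_filter(random_dna(174)))
  expect_false(length_filter(random_dna(173)))
  expect_true(length_filter(random_dna(220)))
  expect_false(length_filter(random_dna(221)))
  expect_true(length_filter(random_dna(200)))
})

test_that("match_read agrees with a full DP alignment against every member", {
  set.seed(21)
  # small synthetic library of unrelated members
  membs <- vapply(1:8, function(i) random_dna(200), "")
  lib <- structure(list(
    members = data.frame(member_id = sprintf("m%02d", 1:8), role = "control",
                         tile_start = NA_integer_,
                         pam_center_offset = NA_integer_, shl = NA_real_,
                         sequence = membs, stringsAsFactors = FALSE),
    backbone = membs[1], frame = default_frame()), class = "nuc_library")
  for (case in 1:12) {
    src <- sample(8, 1)
    start <- sample(1:20, 1)
    len <- sample(150:180, 1)
    readc <- chars(substr(membs[src], start, start + len - 1))
    nmm <- sample(0:4, 1)
    if (nmm > 0) {
      idx <- sample(length(readc), nmm)
      readc[idx] <- vapply(readc[idx], function(b)
        sample(setdiff(c("A", "C", "G", "T"), b), 1), "")
    }
    read <- paste(readc, collapse = "")
    got <- match_read(read, lib)
    want <- match_oracle(read, lib)
    expect_identical(got$status, want$status, label = paste("case", case))
    if (got$status == "assigned") {
      expect_identical(got$member_id, want$member_id)
      expect_equal(got$identity, want$identity, tolerance = 1e-9)
    }
  }
})

test_that("matcher thresholds are inclusive and failures are statuses", {
  lib <- toy_library()
  mem <- lib$members$sequence[1]
  id1 <- lib$members$member_id[1]
  # exact internal 180-nt window
  r <- substr(mem, 21, 200)
  got <- match_read(r, lib)
  expect_identical(got$status, "assigned")
  expect_identical(got$member_id, id1)
  expect_equal(got$identity, 1)
  # 149-col perfect alignment fails the column threshold
  short <- match_read(substr(mem, 21, 169), lib)
  expect_identical(short$status, "too_short_alignment")
  # exactly 150 cols is accepted
  at150 <- match_read(substr(mem, 21, 170), lib)
  expect_identical(at150$status, "assigned")
  # 3 mismatches over 180 cols: 177/180 = 0.9833 < 0.985
  rc3 <- chars(r)
  rc3[c(60, 90, 120)] <- vapply(rc3[c(60, 90, 120)], function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], "")
  low <- match_read(paste(rc3, collapse = ""), lib)
  expect_identical(low$status, "low_identity")
  expect_equal(low$identity, 177 / 180, tolerance = 1e-9)
  # an identical sequence present twice is ambiguous
  lib2 <- lib
  dup <- lib2$members[1, ]
  dup$member_id <- "dup"
  lib2$members <- rbind(lib2$members, dup)
  expect_identical(match_read(r, lib2)$status, "ambiguous")
})

test_that("count tallies conserve totals and ignore input order", {
  lib <- toy_library()
  ids <- lib$members$member_id
  set.seed(3)
  res <- c(
    lapply(sample(ids[1:4], 30, TRUE), function(i)
      list(member_id = i, identity = 1, aligned_cols = 190L,
           status = "assigned")),
    replicate(5, list(member_id = NA, identity = 0.9, aligned_cols = 190L,
                      status = "low_identity"), simplify = FALSE)
  )
  tab <- count_reads(res, lib, sample = "digested", replicate = 2L)
  expect_identical(sum(tab$count) + sum(attr(tab, "rejections")), 35L)
  tab2 <- count_reads(rev(res), lib, sample = "digested", replicate = 2L)
  expect_identical(tab$count, tab2$count)
  expect_identical(unique(tab$sample), "digested")
})

test_that("FASTQ pairs round-trip through files", {
  set.seed(17)
  pairs <- lapply(1:5, function(i)
    list(r1 = nuc_read(random_dna(50), sample(2:40, 50, TRUE)),
         r2 = nuc_read(random_dna(50), sample(2:40, 50, TRUE))))
  f1 <- withr::local_tempfile(fileext = ".fastq")
  f2 <- withr::local_tempfile(fileext = ".fastq")
  write_fastq_pairs(pairs, f1, f2)
  back <- read_fastq_pairs(f1, f2)
  expect_identical(length(back), 5L)
  for (i in 1:5) {
    expect_identical(back[[i]]$r1$seq, pairs[[i]]$r1$seq)
    expect_identical(back[[i]]$r1$qual, pairs[[i]]$r1$qual)
    expect_identical(back[[i]]$r2$qual, pairs[[i]]$r2$qual)
  }
})
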