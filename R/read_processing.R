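#' A sequencing read
#'
#' Minimal container for a read: sequence plus per-base Phred qualities.
#'
#' @param seq DNA string (may contain N).
#' @param qual Integer vector of Phred scores, one per base, or a single
#'   value recycled to the read length.
#' @return A `nuc_read` object (list with `seq`, `qual`).
#' @export
nuc_read <- function(seq, qual) {
  seq <- toupper(seq)
  if (length(qual) == 1L) qual <- rep(as.integer(qual), nchar(seq))
  qual <- as.integer(qual)
  if (nchar(seq) != length(qual))
    stop("seq and qual must have equal length")
  if (any(qual < 0L)) stop("qualities must be >= 0")
  structure(list(seq = seq, qual = qual), class = "nuc_read")
}

#' 3' quality trimming by the running-partial-sum rule
#'
#' Implements the classic BWA-style rule used for 3'-end quality trimming:
#' walking from the 3' end, accumulate `q_cutoff - q` per base and cut at
#' the position where the partial sum is maximal (equivalently, where the
#' partial sum of `q - q_cutoff` is minimal and negative). A read whose
#' qualities are all at or above the cutoff is returned unchanged; a read
#' may be trimmed to empty.
#'
#' @param read A [nuc_read()].
#' @param q_cutoff Phred quality cutoff (default 30).
#' @return The trimmed [nuc_read()].
#' @export
quality_trim_3prime <- function(read, q_cutoff = 30L) {
  n <- length(read$qual)
  if (n == 0L) return(read)
  s <- 0L
  smin <- 0L
  cut <- n + 1L
  for (i in n:1) {
    s <- s + read$qual[i] - q_cutoff
    if (s < smin) {
      smin <- s
      cut <- i
    }
  }
  if (cut > n) return(read)
  nuc_read(substr(read$seq, 1L, cut - 1L), read$qual[seq_len(cut - 1L)])
}

# character vectors of one read, as raw-comparable letters
.chars <- function(seq) strsplit(seq, "", fixed = TRUE)[[1]]

#' Merge a read pair by overlap
#'
#' Reverse-complements the second read, then considers every possible
#' 3'-overlap length between read 1 and the reverse-complemented read 2.
#' Among overlaps with at most `max_diffs` mismatches, the longest is
#' chosen (the enumeration visits longer overlaps first, so ties cannot
#' arise on length; among equal lengths fewer mismatches would win). The
#' merge is rejected — with a reason code rather than an error — when no
#' overlap satisfies the mismatch bound (`"too_many_diffs"`), the best
#' satisfying overlap is shorter than `min_overlap`
#' (`"too_short_overlap"`), or either read is empty (`"no_overlap"`).
#'
#' At agreeing overlap columns the consensus base keeps the higher of the
#' two qualities; at disagreements the higher-quality base wins with its
#' own quality, and an exact quality tie yields `N` with quality 2.
#'
#' @param r1,r2 [nuc_read()]s; `r2` in sequencing orientation (it is
#'   reverse-complemented internally).
#' @param min_overlap Minimum overlap length in nt (default 20).
#' @param max_diffs Maximum mismatches tolerated in the overlap (default 2).
#' @return On success a `merged_read` (list `seq`, `qual`, `overlap_len`,
#'   `n_diffs`, `merged = TRUE`); on rejection a list with
#'   `merged = FALSE` and `reason`.
#' @export
merge_pair <- function(r1, r2, min_overlap = 20L, max_diffs = 2L) {
  n1 <- nchar(r1$seq)
  n2 <- nchar(r2$seq)
  if (n1 == 0L || n2 == 0L)
    return(list(merged = FALSE, reason = "no_overlap"))
  rc2 <- revcomp(r2$seq)
  q2 <- rev(r2$qual)
  a <- .chars(r1$seq)
  b <- .chars(rc2)
  best_o <- 0L
  best_d <- NA_integer_
  for (o in min(n1, n2):1) {
    d <- sum(a[(n1 - o + 1L):n1] != b[1:o])
    if (d <= max_diffs) {
      best_o <- o
      best_d <- d
      break
    }
  }
  if (best_o == 0L) return(list(merged = FALSE, reason = "too_many_diffs"))
  if (best_o < min_overlap)
    return(list(merged = FALSE, reason = "too_short_overlap"))
  o <- best_o
  i1 <- (n1 - o + 1L):n1
  i2 <- 1:o
  ca <- a[i1]; cb <- b[i2]
  qa <- r1$qual[i1]; qb <- q2[i2]
  cons <- ca
  qc <- pmax(qa, qb)
  mm <- ca != cb
  take_b <- mm & qb > qa
  cons[take_b] <- cb[take_b]
  qc[mm] <- ifelse(qb[mm] > qa[mm], qb[mm], qa[mm])
  tie <- mm & qa == qb
  cons[tie] <- "N"
  qc[tie] <- 2L
  seq <- paste0(substr(r1$seq, 1L, n1 - o), paste(cons, collapse = ""),
                substr(rc2, o + 1L, n2))
  qual <- c(r1$qual[seq_len(n1 - o)], qc, q2[seq_len(n2)[-seq_len(o)]])
  list(seq = seq, qual = qual, overlap_len = o, n_diffs = best_d,
       merged = TRUE)
}

hamming <- function(a, b) sum(.chars(a) != .chars(b))

#' Remove terminal primer sequences
#'
#' Removes a match to `primer_5` at the extreme 5' end and to `primer_3`
#' at the extreme 3' end of the sequence, each allowing up to
#' `floor(max_error_rate * nchar(primer))` mismatches. A sequence without
#' a terminal match is returned untouched.
#'
#' @param seq DNA string.
#' @param primer_5,primer_3 Primer sequences (either may be `NULL`).
#' @param max_error_rate Allowed mismatch fraction of the primer length
#'   (default 0.1).
#' @return The trimmed sequence.
#' @export
trim_primers <- function(seq, primer_5 = NULL, primer_3 = NULL,
                         max_error_rate = 0.1) {
  if (!is.null(primer_5) && nchar(primer_5) > 0L) {
    k <- nchar(primer_5)
    if (nchar(seq) >= k &&
        hamming(substr(seq, 1L, k), primer_5) <= floor(max_error_rate * k))
      seq <- substr(seq, k + 1L, nchar(seq))
  }
  if (!is.null(primer_3) && nchar(primer_3) > 0L) {
    k <- nchar(primer_3)
    n <- nchar(seq)
    if (n >= k &&
        hamming(substr(seq, n - k + 1L, n), primer_3) <=
          floor(max_error_rate * k))
      seq <- substr(seq, 1L, n - k)
  }
  seq
}

#' Length filter for merged amplicon reads
#'
#' Keeps sequences whose length lies in `[min_len, max_len]`; sequences
#' strictly shorter than `min_len` or strictly longer than `max_len` are
#' removed, so both bounds are inclusive.
#'
#' @param seq DNA string(s).
#' @param min_len,max_len Inclusive bounds (defaults 174 and 220 nt).
#' @return Logical: `TRUE` to keep.
#' @export
length_filter <- function(seq, min_len = 174L, max_len = 220L) {
  n <- nchar(seq)
  n >= min_len & n <= max_len
}

# Semiglobal alignment of one read against each member: global in the
# read, terminal overhangs of the member free (identity is computed over
# the aligned region only, so a wrong member cannot hide its differing
# window in a free overhang). Returns cbind(identity, cols).
# Scoring: match +1, mismatch -2, linear gap -2.
.align_stats <- function(read, subject_set) {
  aln <- Biostrings::pairwiseAlignment(
    pattern = subject_set, subject = Biostrings::DNAString(read),
    type = "local-global",
    substitutionMatrix = Biostrings::nucleotideSubstitutionMatrix(
      match = 1, mismatch = -2, baseOnly = FALSE),
    gapOpening = 0, gapExtension = 2)
  cols <- nchar(as.character(Biostrings::pattern(aln)))  # aligned cols incl. gaps
  matches <- Biostrings::nmatch(aln)
  cbind(identity = ifelse(cols > 0, matches / cols, 0), cols = cols)
}

#' Assign a read to its best-matching library member
#'
#' Aligns the sequence against every library member with a semiglobal
#' alignment — global in the read, with the member's terminal overhangs
#' free — and keeps the hit with the highest identity, where identity is
#' matching columns / alignment columns (internal gaps count as columns;
#' the member's terminal overhangs are excluded). The hit is reported as
#' `assigned` only if identity is at least `min_identity` and the aligned
#' region spans at least `min_cols` columns — both thresholds inclusive,
#' since rejection is strictly-less-than. Reads whose best identity is
#' attained by more than one distinct member are `ambiguous` and not
#' counted; adjacent tiling members differ by few bases, so ambiguity is a
#' legitimate outcome rather than an error.
#'
#' An exact-substring fast path (identity 1 over the full read) is tried
#' before the alignment; it cannot change the outcome because identity 1
#' at maximal column count is the best attainable hit.
#'
#' @param seq Merged, primer-trimmed DNA string.
#' @param library A `nuc_library`.
#' @param min_identity Minimum identity fraction (default 0.985).
#' @param min_cols Minimum alignment length in columns (default 150).
#' @return A `match_result` list: `member_id` (or `NA`), `identity`,
#'   `aligned_cols`, `status` in `assigned`, `ambiguous`, `no_hit`,
#'   `too_short_alignment`, `low_identity`.
#' @export
match_read <- function(seq, library, min_identity = 0.985,
                       min_cols = 150L) {
  members <- library$members
  if (nrow(members) == 0L) stop("library has no members")
  subject_set <- library_dna(library)
  n <- nchar(seq)
  if (n == 0L)
    return(list(member_id = NA_character_, identity = 0,
                aligned_cols = 0L, status = "no_hit"))
  exact <- Biostrings::vcountPattern(seq, subject_set) > 0L
  if (any(exact)) {
    ids <- members$member_id[exact]
    if (length(ids) > 1L)
      return(list(member_id = NA_character_, identity = 1,
                  aligned_cols = n, status = "ambiguous"))
    if (n < min_cols)
      return(list(member_id = NA_character_, identity = 1,
                  aligned_cols = n, status = "too_short_alignment"))
    return(list(member_id = ids, identity = 1, aligned_cols = n,
                status = "assigned"))
  }
  st <- .align_stats(seq, subject_set)
  best <- max(st[, "identity"])
  hits <- which(st[, "identity"] >= best - 1e-12)
  if (best <= 0)
    return(list(member_id = NA_character_, identity = 0,
                aligned_cols = 0L, status = "no_hit"))
  if (length(hits) > 1L)
    return(list(member_id = NA_character_, identity = best,
                aligned_cols = as.integer(st[hits[1L], "cols"]),
                status = "ambiguous"))
  cols <- as.integer(st[hits, "cols"])
  id <- st[hits, "identity"]
  status <- if (cols < min_cols) "too_short_alignment"
            else if (id < min_identity) "low_identity"
            else "assigned"
  list(member_id = if (status == "assigned") members$member_id[hits]
                   else NA_character_,
       identity = unname(id), aligned_cols = cols, status = status)
}

# cached DNAStringSet view of the library members
library_dna <- function(library) {
  cache <- attr(library, ".dna_cache")
  if (!is.null(cache)) return(cache)
  Biostrings::DNAStringSet(stats::setNames(library$members$sequence,
                                           library$members$member_id))
}

#' Tally match results into a per-member count table
#'
#' @param match_results List of [match_read()] results from one sample.
#' @param library A `nuc_library` (fixes the member universe so unseen
#'   members appear with count 0).
#' @param sample,replicate Labels attached to the output rows.
#' @return A data.frame (`member_id`, `sample`, `replicate`, `count`) with
#'   attribute `rejections`: named integer vector of non-assigned statuses.
#'   Assigned counts plus rejections sum to the number of inputs.
#' @export
count_reads <- function(match_results, library, sample = "sample",
                        replicate = 1L) {
  statuses <- vapply(match_results, `[[`, character(1), "status")
  ids <- vapply(match_results, function(r)
    if (identical(r$status, "assigned")) r$member_id else NA_character_,
    character(1))
  counts <- table(factor(ids[!is.na(ids)],
                         levels = library$members$member_id))
  rej <- table(factor(statuses[statuses != "assigned"],
                      levels = c("ambiguous", "no_hit",
                                 "too_short_alignment", "low_identity")))
  out <- data.frame(member_id = names(counts), sample = sample,
                    replicate = as.integer(replicate),
                    count = as.integer(counts), stringsAsFactors = FALSE)
  attr(out, "rejections") <- stats::setNames(as.integer(rej), names(rej))
  out
}

#' Run the full read pipeline on a set of read pairs
#'
#' Applies, in order: 3' quality trimming of both mates (q >= `q_cutoff`),
#' overlap merging (>= `min_overlap` nt overlap, <= `max_diffs`
#' mismatches), terminal primer removal, inclusive length filtering
#' (`min_len`..`max_len` nt), and identity-based assignment to the library
#' (>= `min_cols` columns, >= `min_identity` identity, best hit only, ties
#' discarded). Every input pair ends in exactly one terminal status.
#'
#' @param pairs List of pairs; each element a list with `r1`, `r2`
#'   ([nuc_read()]s), e.g. from [read_fastq_pairs()] or
#'   [simulate_reads()].
#' @param library A `nuc_library`.
#' @param primer_5,primer_3 Primers flanking the construct (defaults: the
#'   terminal 20 bp of the library backbone on each side).
#' @param q_cutoff,min_overlap,max_diffs,max_error_rate,min_len,max_len,min_identity,min_cols
#'   Stage thresholds; defaults are the pipeline's standard values
#'   (q30; 20/2; 0.1; 174/220; 0.985/150).
#' @param sample,replicate Labels for the count table.
#' @return List with `counts` (see [count_reads()]) and `report`: named
#'   integer vector of per-stage outcomes (`input`, `merge_*`,
#'   `too_short`/`too_long` length failures, match statuses, `assigned`).
#' @export
process_reads <- function(pairs, library,
                          primer_5 = NULL, primer_3 = NULL,
                          q_cutoff = 30L, min_overlap = 20L, max_diffs = 2L,
                          max_error_rate = 0.1,
                          min_len = 174L, max_len = 220L,
                          min_identity = 0.985, min_cols = 150L,
                          sample = "sample", replicate = 1L) {
  if (is.null(primer_5))
    primer_5 <- substr(library$backbone, 1L, 20L)
  if (is.null(primer_3)) {
    L <- nchar(library$backbone)
    primer_3 <- substr(library$backbone, L - 19L, L)
  }
  report <- c(input = length(pairs), merge_no_overlap = 0L,
              merge_too_many_diffs = 0L, merge_too_short_overlap = 0L,
              too_short = 0L, too_long = 0L, ambiguous = 0L, no_hit = 0L,
              too_short_alignment = 0L, low_identity = 0L, assigned = 0L)
  results <- vector("list", length(pairs))
  kept <- 0L
  for (p in pairs) {
    r1 <- quality_trim_3prime(p$r1, q_cutoff)
    r2 <- quality_trim_3prime(p$r2, q_cutoff)
    m <- merge_pair(r1, r2, min_overlap, max_diffs)
    if (!m$merged) {
      key <- paste0("merge_", m$reason)
      report[key] <- report[key] + 1L
      next
    }
    seq <- trim_primers(m$seq, primer_5, primer_3, max_error_rate)
    if (nchar(seq) < min_len) { report["too_short"] <- report["too_short"] + 1L; next }
    if (nchar(seq) > max_len) { report["too_long"] <- report["too_long"] + 1L; next }
    res <- match_read(seq, library, min_identity, min_cols)
    report[res$status] <- report[res$status] + 1L
    if (res$status == "assigned") {
      kept <- kept + 1L
      results[[kept]] <- res
    }
  }
  counts <- count_reads(results[seq_len(kept)], library, sample, replicate)
  attr(counts, "rejections") <-
    report[c("ambiguous", "no_hit", "too_short_alignment", "low_identity")]
  list(counts = counts, report = report)
}

#' Read paired FASTQ files
#'
#' @param path1,path2 FASTQ paths (gzip allowed) for mates 1 and 2.
#' @return A list of pairs, each `list(r1 = , r2 = )` of [nuc_read()]s.
#' @export
read_fastq_pairs <- function(path1, path2) {
  rd <- function(path) {
    # reading + coercions drop the (unused) mcols; silence that note
    suppressWarnings({
      x <- Biostrings::readQualityScaledDNAStringSet(path)
      list(seq = unname(as.character(x)),
           qual = as(Biostrings::quality(x), "IntegerList"))
    })
  }
  a <- rd(path1)
  b <- rd(path2)
  if (length(a$seq) != length(b$seq))
    stop("paired FASTQ files differ in read count")
  lapply(seq_along(a$seq), function(i)
    list(r1 = nuc_read(a$seq[i], as.integer(a$qual[[i]])),
         r2 = nuc_read(b$seq[i], as.integer(b$qual[[i]]))))
}

#' Write read pairs to a pair of FASTQ files
#'
#' @param pairs List of pairs as produced by [simulate_reads()].
#' @param path1,path2 Output FASTQ paths.
#' @return `c(path1, path2)`, invisibly.
#' @export
write_fastq_pairs <- function(pairs, path1, path2) {
  wr <- function(reads, ids, path) {
    seqs <- Biostrings::DNAStringSet(vapply(reads, `[[`, character(1), "seq"))
    quals <- Biostrings::PhredQuality(
      vapply(reads, function(r)
        rawToChar(as.raw(pmin(r$qual, 93L) + 33L)), character(1)))
    x <- Biostrings::QualityScaledDNAStringSet(seqs, quals)
    names(x) <- ids
    Biostrings::writeQualityScaledXStringSet(x, path)
  }
  ids <- sprintf("read_%06d", seq_along(pairs))
  wr(lapply(pairs, `[[`, "r1"), ids, path1)
  wr(lapply(pairs, `[[`, "r2"), ids, path2)
  invisible(c(path1, path2))
}
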