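#' Per-base-pair fragment coverage
#'
#' Counts, for every base pair of a member, the number of fragments whose
#' interval contains it. Intervals are 0-based half-open `[start, end)`.
#' Coverage mass is conserved: the column sums equal the total fragment
#' length.
#'
#' @param fragments data.frame with `start`, `end` (0-based half-open),
#'   optionally `member_id` (must be a single member).
#' @param member_len Length of the member sequence in bp.
#' @return Integer vector of length `member_len`; element `i` is the
#'   coverage of 0-based position `i - 1`.
#' @export
fragment_coverage <- function(fragments, member_len) {
  if (!is.null(fragments$member_id) &&
      length(unique(fragments$member_id)) > 1L)
    stop("fragments span more than one member")
  if (nrow(fragments) == 0L) return(integer(member_len))
  bad <- which(fragments$start < 0L | fragments$end > member_len |
               fragments$start >= fragments$end)
  if (length(bad))
    stop(sprintf("fragment %d has interval [%d, %d) outside [0, %d)",
                 bad[1L], fragments$start[bad[1L]], fragments$end[bad[1L]],
                 member_len))
  cov <- IRanges::coverage(
    IRanges::IRanges(start = fragments$start + 1L, end = fragments$end),
    width = member_len)
  as.integer(cov)
}

#' Per-base-pair MNase protection
#'
#' The fraction of a member's reads covering each base pair: coverage
#' divided by the member's own total read (fragment) count. Values lie in
#' `[0, 1]`; 1 means every fragment of that member spans the position
#' (fully protected), 0 means no fragment does.
#'
#' @param coverage Integer coverage vector (from [fragment_coverage()]).
#' @param total_reads Total number of fragments for this member (>= 1).
#' @return Numeric vector of per-bp protection fractions.
#' @export
mnase_protection <- function(coverage, total_reads) {
  if (total_reads < 1L) stop("total_reads must be >= 1")
  coverage / total_reads
}

#' MNase protection track for one member
#'
#' Convenience wrapper: coverage then protection, with `total_reads`
#' defaulting to the member's own fragment count.
#'
#' @inheritParams fragment_coverage
#' @param total_reads Override for the fragment count (default
#'   `nrow(fragments)`).
#' @return A `coverage_track` data.frame: `bp` (0-based), `coverage`,
#'   `protection`, with attribute `total_reads`.
#' @export
mnase_track <- function(fragments, member_len,
                        total_reads = nrow(fragments)) {
  cov <- fragment_coverage(fragments, member_len)
  out <- data.frame(bp = seq_len(member_len) - 1L, coverage = cov,
                    protection = mnase_protection(cov, total_reads))
  attr(out, "total_reads") <- total_reads
  class(out) <- c("coverage_track", "data.frame")
  out
}

#' Mean MNase protection in a window around an SHL
#'
#' @param track A `coverage_track` (from [mnase_track()]).
#' @param frame A [nucleosome_frame()].
#' @param shl Centre of the window, in SHL units.
#' @param halfwidth Window half-width in bp (default 5, i.e. half an SHL
#'   period each side).
#' @return Mean protection over the window.
#' @export
mnase_window_mean <- function(track, frame, shl, halfwidth = 5L) {
  center <- frame$dyad_offset + offset_of_shl(shl, frame)
  sel <- track$bp >= center - halfwidth & track$bp <= center + halfwidth
  if (!any(sel)) stop("window falls outside the track")
  mean(track$protection[sel])
}

#' Join a Cas9 protection profile with an MNase track
#'
#' Produces one row per position carrying both measures on the shared
#' coordinate frame: the Cas9 profile is keyed by the backbone position of
#' the PAM centre (dyad offset + frame dyad), the MNase track by bp.
#' Positions present in only one input carry `NA` for the other measure.
#'
#' @param cas9_profile A `protection_profile` (from
#'   [profile_by_position()]); its `frame` is assumed to be `frame`.
#' @param track A `coverage_track`.
#' @param frame The shared [nucleosome_frame()].
#' @return data.frame `bp` (0-based backbone position), `shl`,
#'   `cas9_z`, `cas9_raw`, `mnase_protection`; full outer join.
#' @export
align_profiles <- function(cas9_profile, track, frame = default_frame()) {
  stopifnot(inherits(frame, "nucleosome_frame"))
  cas_bp <- cas9_profile$pam_center_offset + frame$dyad_offset
  cas <- data.frame(bp = cas_bp, cas9_z = cas9_profile$z_mean,
                    cas9_raw = cas9_profile$raw_mean)
  mn <- data.frame(bp = track$bp, mnase_protection = track$protection)
  out <- merge(cas, mn, by = "bp", all = TRUE)
  out$shl <- shl_of_offset(out$bp - frame$dyad_offset, frame)
  out <- out[order(out$bp),
             c("bp", "shl", "cas9_z", "cas9_raw", "mnase_protection")]
  rownames(out) <- NULL
  out
}

#' Read MNase fragments from a BED-like TSV
#'
#' Expects at least three columns: member id, 0-based start, half-open
#' end; extra columns are ignored.
#'
#' @param path TSV path (no header or a `member_id/start/end` header).
#' @return data.frame `member_id`, `start`, `end`.
#' @export
read_fragments_tsv <- function(path) {
  first <- readLines(path, n = 1L)
  header <- grepl("start", first, fixed = TRUE)
  x <- utils::read.table(path, sep = "\t", header = header,
                         stringsAsFactors = FALSE)
  x <- x[, 1:3]
  names(x) <- c("member_id", "start", "end")
  x$start <- as.integer(x$start)
  x$end <- as.integer(x$end)
  x
}

#' Write MNase fragments as BED-like TSV
#' @param fragments data.frame `member_id`, `start`, `end`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fragments_tsv <- function(fragments, path) {
  utils::write.table(fragments[, c("member_id", "start", "end")], path,
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  invisible(path)
}
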