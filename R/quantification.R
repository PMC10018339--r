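#' Protection from Cas9
#'
#' The per-member protection statistic: the log2 ratio of
#' control-normalised uncleaved read counts, digested over undigested,
#'
#' \deqn{\log_2\!\left(\frac{D_N / D_{CON}}{U_N / U_{CON}}\right)}
#'
#' where \eqn{D_N}/\eqn{U_N} are the uncleaved read counts of a member in
#' the Cas9-digested and undigested pools and \eqn{D_{CON}}/\eqn{U_{CON}}
#' the counts of the native Widom 601 control, which absorbs technical
#' variability from PCR, library construction and sequencing. A value of 0
#' means no Cas9-specific depletion; increasingly negative values mean
#' increasing cleavage. The statistic is antisymmetric under swapping the
#' digested and undigested pools and invariant to rescaling all counts of
#' one pool.
#'
#' @param rd_n Digested count(s) of the member(s) (vectorised).
#' @param rd_con Digested count of the control.
#' @param ru_n Undigested count(s) of the member(s).
#' @param ru_con Undigested count of the control.
#' @param pseudocount Added to all four counts before the ratio (default
#'   1); with 0 every count involved must be positive.
#' @return Numeric protection value(s).
#' @export
#' @examples
#' protection_from_cas9(10, 100, 40, 100, pseudocount = 0)  # -2
protection_from_cas9 <- function(rd_n, rd_con, ru_n, ru_con,
                                 pseudocount = 1) {
  if (pseudocount < 0) stop("pseudocount must be >= 0")
  if (any(c(rd_n, rd_con, ru_n, ru_con) < 0)) stop("counts must be >= 0")
  rd_n <- rd_n + pseudocount
  rd_con <- rd_con + pseudocount
  ru_n <- ru_n + pseudocount
  ru_con <- ru_con + pseudocount
  if (any(rd_con == 0) || any(ru_con == 0) || any(ru_n == 0))
    stop("zero denominator with pseudocount 0; use a positive pseudocount")
  log2((rd_n / rd_con) / (ru_n / ru_con))
}

# population standard deviation
.pop_sd <- function(x) sqrt(mean((x - mean(x))^2))

#' Z-score normalisation against nonspecific background members
#'
#' Standardises raw protection values by the mean and (population)
#' standard deviation of the background members, so the background itself
#' has mean 0 and SD 1 by construction.
#'
#' @param raw Named numeric vector of raw protection values (names =
#'   member ids).
#' @param background_ids Ids of the background members.
#' @return Named numeric vector of Z values, same order as `raw`.
#' @export
zscore_normalize <- function(raw, background_ids) {
  bg <- raw[names(raw) %in% background_ids]
  bg <- bg[is.finite(bg)]
  if (length(bg) < 2L)
    stop("need at least 2 background members with finite values")
  s <- .pop_sd(bg)
  if (s == 0) stop("background standard deviation is 0")
  (raw - mean(bg)) / s
}

#' Per-replicate protection values for a count table
#'
#' Computes the raw protection statistic for every member in every
#' replicate, then Z-normalises each replicate against its own background
#' members (normalisation is per sample, before any averaging across
#' replicates).
#'
#' @param counts Long count table: data.frame with `member_id`, `sample`
#'   (`"digested"` / `"undigested"`), `replicate`, `count` — e.g. from
#'   [simulate_counts()] or stacked [process_reads()] outputs.
#' @param library A `nuc_library`.
#' @param control_id Id of the native backbone control (default
#'   `"control"`).
#' @param background_role Role marking background members (default
#'   `"background"`).
#' @param pseudocount Passed to [protection_from_cas9()] (default 1).
#' @return data.frame `member_id`, `replicate`, `raw`, `z`.
#' @export
compute_protection <- function(counts, library, control_id = "control",
                               background_role = "background",
                               pseudocount = 1) {
  members <- library$members
  if (!control_id %in% members$member_id)
    stop("control member '", control_id, "' not in library")
  bg_ids <- members$member_id[members$role == background_role]
  reps <- sort(unique(counts$replicate))
  out <- lapply(reps, function(r) {
    d <- counts[counts$replicate == r & counts$sample == "digested", ]
    u <- counts[counts$replicate == r & counts$sample == "undigested", ]
    dd <- stats::setNames(d$count, d$member_id)
    uu <- stats::setNames(u$count, u$member_id)
    ids <- members$member_id
    missing <- ids[!(ids %in% names(dd)) | !(ids %in% names(uu))]
    if (length(missing))
      stop("member(s) absent from replicate ", r, " counts: ",
           paste(utils::head(missing, 3), collapse = ", "))
    raw <- protection_from_cas9(dd[ids], dd[[control_id]],
                                uu[ids], uu[[control_id]], pseudocount)
    names(raw) <- ids
    z <- zscore_normalize(raw, bg_ids)
    data.frame(member_id = ids, replicate = r, raw = unname(raw),
               z = unname(z), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' SHL-indexed protection profile
#'
#' Joins per-replicate protection values to the library design, keeps the
#' requested role(s), and aggregates across replicates: one row per tiling
#' position, ordered by SHL, with replicate mean and standard error of the
#' mean for both the raw and Z-normalised statistics.
#'
#' @param protection Output of [compute_protection()] (or any data.frame
#'   with `member_id`, `replicate`, `raw`, `z`).
#' @param library A `nuc_library`.
#' @param role_filter Role(s) to keep (e.g. `"forward_target"`).
#' @return A `protection_profile` data.frame: `member_id`, `role`,
#'   `tile_start`, `pam_center_offset`, `shl`, `n_rep`, `raw_mean`,
#'   `raw_sem`, `z_mean`, `z_sem`, sorted by `shl`.
#' @export
profile_by_position <- function(protection, library,
                                role_filter = c("forward_target",
                                                "reverse_target",
                                                "nontarget")) {
  members <- library$members
  unknown <- setdiff(protection$member_id, members$member_id)
  if (length(unknown))
    stop("member(s) missing from library metadata: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  keep_ids <- members$member_id[members$role %in% role_filter]
  p <- protection[protection$member_id %in% keep_ids, , drop = FALSE]
  sem <- function(x) if (length(x) < 2L) 0 else
    stats::sd(x) / sqrt(length(x))
  agg <- lapply(split(p, p$member_id), function(g) {
    data.frame(member_id = g$member_id[1L], n_rep = nrow(g),
               raw_mean = mean(g$raw), raw_sem = sem(g$raw),
               z_mean = mean(g$z), z_sem = sem(g$z),
               stringsAsFactors = FALSE)
  })
  agg <- do.call(rbind, agg)
  idx <- match(agg$member_id, members$member_id)
  out <- cbind(members[idx, c("member_id", "role", "tile_start",
                              "pam_center_offset", "shl")],
               agg[, c("n_rep", "raw_mean", "raw_sem", "z_mean", "z_sem")])
  out <- out[order(out$shl, out$role), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("protection_profile", "data.frame")
  out
}

#' Pairwise replicate correlation
#'
#' Pearson correlation of log2(count + 1) per member between every pair of
#' samples/replicates in a long count table.
#'
#' @param counts Long count table (`member_id`, `sample`, `replicate`,
#'   `count`).
#' @return Symmetric correlation matrix with unit diagonal, one row/column
#'   per `sample.replicate` combination; entries involving a constant
#'   count vector are `NA`.
#' @export
replicate_correlation <- function(counts) {
  key <- paste(counts$sample, counts$replicate, sep = ".")
  if (length(unique(key)) < 2L) stop("need at least 2 samples")
  wide <- stats::xtabs(count ~ member_id + key,
                       data = cbind(counts, key = key))
  x <- log2(unclass(wide) + 1)
  suppressWarnings(cc <- stats::cor(x))
  diag(cc) <- 1
  cc
}

#' Write a protection profile to TSV
#' @param profile A `protection_profile`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  utils::write.table(profile, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
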