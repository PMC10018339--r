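#' Parametric nucleosome digestion model
#'
#' A stand-in protection-versus-position model used to generate synthetic
#' digestion data: cleavage probability rises logistically as the PAM
#' centre moves from the dyad past the nucleosome edge into the linker.
#' The functional form is a deliberately simple two-parameter monotone
#' curve chosen to be recoverable by fitting; it parametrises behaviour
#' the assay measures but does not itself model Cas9 biophysics.
#'
#' * `edge_offset` — bp from the dyad at which accessibility transitions
#'   (logistic midpoint; default 73, the edge of a 147-bp wrap).
#' * `steepness` — logistic slope in 1/bp.
#' * `max_cleavage` — cleavage probability in the fully accessible limit.
#' * `orientation_shift` — extra bp of protection for forward-orientation
#'   targets (PAM 3' of target, so the buried target delays cleavage);
#'   shifts the forward midpoint outward (default 6).
#' * `mismatch_penalty` — named map from sgRNA/target mismatch position
#'   (PAM-distal bases, e.g. `"19"`, `"20"`) to a multiplicative cleavage
#'   factor in `[0, 1]`; a PAM-proximal-ward mismatch penalises cleavage
#'   more (smaller factor).
#' * `nontarget_cleavage` — baseline probability for members without a
#'   complementary target (nontarget, control, background).
#'
#' @param edge_offset,steepness,max_cleavage,orientation_shift,mismatch_penalty,nontarget_cleavage
#'   See above.
#' @return A `digestion_model` object.
#' @export
digestion_model <- function(edge_offset = 73, steepness = 0.8,
                            max_cleavage = 0.95, orientation_shift = 6,
                            mismatch_penalty = c("19" = 0.30, "20" = 0.60),
                            nontarget_cleavage = 0.02) {
  stopifnot(steepness > 0,
            max_cleavage >= 0, max_cleavage <= 1,
            nontarget_cleavage >= 0, nontarget_cleavage <= 1,
            all(mismatch_penalty >= 0), all(mismatch_penalty <= 1))
  structure(list(edge_offset = edge_offset, steepness = steepness,
                 max_cleavage = max_cleavage,
                 orientation_shift = orientation_shift,
                 mismatch_penalty = mismatch_penalty,
                 nontarget_cleavage = nontarget_cleavage),
            class = "digestion_model")
}

#' Simulation configuration
#'
#' @param n_reads Reads per sample (default 1e5, the depth at which the
#'   protection statistic and edge fit are well resolved).
#' @param error_rate Per-base substitution error rate in `[0, 0.5)`.
#' @param read_length Read length in nt (default 150, paired 2x150).
#' @param n_replicates Replicate count (default 3, matching a triplicate
#'   digestion design).
#' @param seed Top-level RNG seed (mandatory); per-replicate streams are
#'   derived deterministically from it.
#' @param error_profile How the per-base error mass is laid out along the
#'   read, with qualities encoding the per-base error probability:
#'   `"tail"` (default) emulates the Illumina pattern of errors
#'   concentrating at the 3' end — interior bases carry quality 38
#'   (error 10^-3.8) and a 3' tail of `round(read_length * error_rate /
#'   0.5)` bases carries quality 2 (error 0.5), so 3' quality trimming
#'   removes essentially all of the error mass before merging;
#'   `"uniform"` places errors uniformly at `error_rate` with constant
#'   quality 40 (qualities then deliberately do not flag the errors),
#'   which is the adversarial layout used to stress matching.
#' @return A `sim_config` object.
#' @export
sim_config <- function(n_reads = 1e5, error_rate = 0, read_length = 150L,
                       n_replicates = 3L, seed,
                       error_profile = c("tail", "uniform")) {
  if (missing(seed)) stop("seed is mandatory")
  error_profile <- match.arg(error_profile)
  stopifnot(n_reads > 0, error_rate >= 0, error_rate < 0.5,
            read_length > 0)
  structure(list(n_reads = as.integer(n_reads), error_rate = error_rate,
                 read_length = as.integer(read_length),
                 n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed),
                 error_profile = error_profile),
            class = "sim_config")
}

# per-base quality and error-probability vectors for one read
.read_error_model <- function(config) {
  rl <- config$read_length
  if (config$error_profile == "uniform") {
    list(qual = rep(40L, rl), perr = rep(config$error_rate, rl))
  } else {
    interior_err <- if (config$error_rate > 0) 10^-3.8 else 0
    t <- min(rl, round(rl * max(config$error_rate - interior_err, 0) / 0.5))
    qual <- rep(38L, rl)
    perr <- rep(interior_err, rl)
    if (t > 0L) {
      tail_idx <- (rl - t + 1L):rl
      qual[tail_idx] <- 2L
      perr[tail_idx] <- 0.5
    }
    list(qual = qual, perr = perr)
  }
}

# derive a 32-bit sub-seed from the top-level seed
.sub_seed <- function(seed, stream) {
  (as.double(seed) * 2654435761 + stream * 97561) %% 2147483647
}

#' Cleavage probability of a library member
#'
#' Deterministic map from a member's design metadata to its probability
#' of being cleaved in the digested sample. Target members follow the
#' logistic accessibility curve in the absolute PAM-centre distance from
#' the dyad, with the midpoint shifted `orientation_shift` bp outward for
#' forward-orientation members; members without a complementary target
#' (nontarget, control, background) sit at the nontarget baseline. A
#' mismatch between sgRNA and target scales the cleavage above baseline
#' by the configured penalty.
#'
#' @param member One row of a library members data.frame (or a data.frame
#'   of rows; vectorised).
#' @param model A [digestion_model()].
#' @param mismatch Optional mismatch position (e.g. `19` or `20`) looked
#'   up in `model$mismatch_penalty`; `NULL` for an on-target sgRNA.
#' @return Cleavage probability/probabilities in `[0, 1]`.
#' @export
cleavage_probability <- function(member, model, mismatch = NULL) {
  stopifnot(inherits(model, "digestion_model"))
  penalty <- 1
  if (!is.null(mismatch)) {
    key <- as.character(mismatch)
    if (!key %in% names(model$mismatch_penalty))
      stop("no penalty configured for mismatch position ", key)
    penalty <- model$mismatch_penalty[[key]]
  }
  role <- member$role
  d <- abs(member$pam_center_offset)
  mid <- model$edge_offset +
    ifelse(role == "forward_target", model$orientation_shift, 0)
  acc <- stats::plogis(model$steepness * (d - mid))
  p_target <- model$nontarget_cleavage +
    (model$max_cleavage * penalty - model$nontarget_cleavage) * acc
  ifelse(role %in% c("forward_target", "reverse_target"),
         p_target, model$nontarget_cleavage)
}

#' Simulate digested/undigested count tables
#'
#' For each replicate, undigested counts are drawn multinomially over the
#' members (uniform abundance unless `abundance` is given); digested
#' counts draw an independent multinomial of the same depth and then thin
#' each member binomially with survival probability `1 - p` where `p` is
#' its [cleavage_probability()]. In expectation the protection statistic
#' of a member is therefore `log2((1 - p) / (1 - p_control))`.
#'
#' @param library A `nuc_library`.
#' @param model A [digestion_model()].
#' @param config A [sim_config()].
#' @param mismatch Passed to [cleavage_probability()].
#' @param abundance Optional per-member relative abundance vector.
#' @return Long count table (`member_id`, `sample`, `replicate`,
#'   `count`) with attribute `truth`: data.frame (`member_id`,
#'   `cleavage_probability`).
#' @export
simulate_counts <- function(library, model, config, mismatch = NULL,
                            abundance = NULL) {
  members <- library$members
  n <- nrow(members)
  p <- cleavage_probability(members, model, mismatch)
  if (is.null(abundance)) abundance <- rep(1, n)
  out <- vector("list", 2L * config$n_replicates)
  k <- 0L
  for (r in seq_len(config$n_replicates)) {
    set.seed(.sub_seed(config$seed, r))
    u <- as.integer(stats::rmultinom(1L, config$n_reads, abundance))
    d0 <- as.integer(stats::rmultinom(1L, config$n_reads, abundance))
    d <- stats::rbinom(n, d0, 1 - p)
    k <- k + 1L
    out[[k]] <- data.frame(member_id = members$member_id,
                           sample = "undigested", replicate = r,
                           count = u, stringsAsFactors = FALSE)
    k <- k + 1L
    out[[k]] <- data.frame(member_id = members$member_id,
                           sample = "digested", replicate = r,
                           count = d, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  attr(res, "truth") <- data.frame(member_id = members$member_id,
                                   cleavage_probability = p,
                                   stringsAsFactors = FALSE)
  res
}

.mutate_bases <- function(chars, idx) {
  alt <- list(A = c("C", "G", "T"), C = c("A", "G", "T"),
              G = c("A", "C", "T"), T = c("A", "C", "G"))
  for (i in idx) {
    from <- chars[i]
    choices <- alt[[from]]
    if (is.null(choices)) choices <- c("A", "C", "G", "T")
    chars[i] <- choices[sample.int(3L, 1L)]
  }
  chars
}

#' Simulate paired reads for a count table sample
#'
#' Emits one read pair per counted molecule: read 1 is the first
#' `read_length` bases of the member, read 2 the reverse complement of
#' the last `read_length` bases, so the mates overlap in the middle of a
#' 230-bp member by `2 * read_length - member length` nt. Substitution
#' errors are placed independently per base according to the config's
#' error profile, and the written qualities encode each base's error
#' probability (see [sim_config()]), so the 3' trimming and
#' quality-aware merge consensus stages act on simulated reads the way
#' they act on real ones.
#'
#' @param counts A count table subset for one sample (columns
#'   `member_id`, `count`), e.g. one `sample`/`replicate` slice of
#'   [simulate_counts()] output.
#' @param library A `nuc_library`.
#' @param config A [sim_config()]; the RNG stream is derived from
#'   `config$seed` and `stream`.
#' @param stream Integer RNG stream discriminator, so different samples
#'   of one experiment get independent reads (default 0).
#' @return List of read pairs (`list(r1 =, r2 =)` of [nuc_read()]s),
#'   suitable for [process_reads()] or [write_fastq_pairs()].
#' @export
simulate_reads <- function(counts, library, config, stream = 0L) {
  members <- library$members
  seqs <- stats::setNames(members$sequence, members$member_id)
  rl <- config$read_length
  set.seed(.sub_seed(config$seed, 1000L + stream))
  pairs <- vector("list", sum(counts$count))
  k <- 0L
  em <- .read_error_model(config)
  qual <- em$qual
  perr <- em$perr
  for (i in seq_len(nrow(counts))) {
    cnt <- counts$count[i]
    if (cnt == 0L) next
    tmpl <- seqs[[counts$member_id[i]]]
    L <- nchar(tmpl)
    if (rl > L) stop("read_length exceeds member length")
    fwd <- .chars(substr(tmpl, 1L, rl))
    rev_ <- .chars(revcomp(substr(tmpl, L - rl + 1L, L)))
    for (j in seq_len(cnt)) {
      c1 <- fwd
      c2 <- rev_
      if (config$error_rate > 0) {
        e1 <- which(stats::runif(rl) < perr)
        e2 <- which(stats::runif(rl) < perr)
        if (length(e1)) c1 <- .mutate_bases(c1, e1)
        if (length(e2)) c2 <- .mutate_bases(c2, e2)
      }
      k <- k + 1L
      pairs[[k]] <- list(
        r1 = nuc_read(paste(c1, collapse = ""), qual),
        r2 = nuc_read(paste(c2, collapse = ""), qual))
    }
  }
  pairs[seq_len(k)]
}

#' Simulate MNase fragments from a per-boundary cut-probability profile
#'
#' Each simulated molecule is cut at its physical termini (positions 0
#' and `L`) and, independently, at every interior boundary `i`
#' (between bases `i - 1` and `i`) with probability `cut_prob[i + 1]`.
#' Consecutive cut sites delimit fragments; fragments shorter than
#' `min_len` are discarded (size selection — the default 100 bp mimics
#' mono-nucleosome selection, so sub-nucleosomal linker scraps drop out
#' and a core with zero interior cut probability yields a protection
#' plateau of exactly 1). Molecules are digested until `n_fragments`
#' fragments have been retained.
#'
#' @param cut_prob Numeric vector of length `L + 1`: cut probability at
#'   boundaries `0..L`. Entries 1 and `L + 1` (the molecule ends) are
#'   treated as always cut.
#' @param n_fragments Number of fragments to return.
#' @param seed RNG seed.
#' @param min_len Minimum retained fragment length in bp (default 100).
#' @param member_id Label for the output fragments.
#' @return data.frame `member_id`, `start`, `end` (0-based half-open).
#' @export
simulate_mnase_fragments <- function(cut_prob, n_fragments, seed,
                                     min_len = 100L,
                                     member_id = "member") {
  L <- length(cut_prob) - 1L
  stopifnot(L >= 1L, all(cut_prob >= 0), all(cut_prob <= 1))
  set.seed(as.integer(seed))
  interior <- seq_len(L - 1L)
  p_int <- cut_prob[interior + 1L]
  starts <- integer(0)
  ends <- integer(0)
  guard <- 0L
  while (length(starts) < n_fragments) {
    guard <- guard + 1L
    if (guard > 100L * n_fragments + 1000L)
      stop("size selection rejects nearly all fragments; lower min_len")
    cuts <- c(0L, interior[stats::runif(L - 1L) < p_int], L)
    s <- cuts[-length(cuts)]
    e <- cuts[-1L]
    keep <- (e - s) >= min_len
    starts <- c(starts, s[keep])
    ends <- c(ends, e[keep])
  }
  data.frame(member_id = member_id, start = starts[seq_len(n_fragments)],
             end = ends[seq_len(n_fragments)], stringsAsFactors = FALSE)
}

#' Recover the accessibility edge from a protection profile by grid search
#'
#' For each candidate `edge_offset` on the grid, predicts the expected
#' raw protection of every target member as
#' `log2((1 - p(d; edge)) / (1 - p_control))` under the model template and
#' returns the candidate minimising the sum of squared deviations from the
#' observed raw protection. With the template's other parameters held at
#' their generating values this is a one-dimensional profile fit; at deep
#' read counts the simulated noise is small and the true edge is
#' recovered to within a couple of bp.
#'
#' @param profile A `protection_profile` restricted to one target role
#'   (from [profile_by_position()]).
#' @param library A `nuc_library` (for member metadata).
#' @param model_template A [digestion_model()] supplying every parameter
#'   except the edge being fitted.
#' @param grid Candidate edge offsets in bp (default 55..95).
#' @param mismatch Passed to [cleavage_probability()].
#' @return List: `edge_offset` (best candidate), `sse` (named vector of
#'   the objective over the grid).
#' @export
fit_edge_offset <- function(profile, library, model_template,
                            grid = 55:95, mismatch = NULL) {
  idx <- match(profile$member_id, library$members$member_id)
  members <- library$members[idx, , drop = FALSE]
  ctrl <- library$members[library$members$role == "control", ][1, ]
  obs <- profile$raw_mean
  sse <- vapply(grid, function(edge) {
    m <- model_template
    m$edge_offset <- edge
    p <- cleavage_probability(members, m, mismatch)
    p_con <- cleavage_probability(ctrl, m, mismatch)
    pred <- log2((1 - p) / (1 - p_con))
    sum((obs - pred)^2)
  }, numeric(1))
  names(sse) <- grid
  list(edge_offset = grid[which.min(sse)], sse = sse)
}
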