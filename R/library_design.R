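#' Cas9 target + PAM motif
#'
#' Describes the combined motif substituted into the backbone at each
#' tiling position. In the forward conformation the NGG PAM lies 3' of the
#' target sequence; in the reverse conformation the PAM lies 5' of the
#' target. A nontarget carries an 18-nt non-complementary sequence 5' of
#' the PAM and acts as a negative control for digestion.
#'
#' @param target_seq DNA string: 20 nt for on-targets, 18 nt for the
#'   nontarget role.
#' @param pam_seq 3-nt PAM, NGG pattern (default "TGG").
#' @param role One of `"forward_target"`, `"reverse_target"`,
#'   `"nontarget"`.
#' @return A `target_motif` object with fields `target_seq`, `pam_seq`,
#'   `orientation` (`forward` when the PAM is 3' of the target, `reverse`
#'   when it is 5'), `role`, and `motif` (the combined sequence as laid
#'   down on the Watson strand).
#' @export
target_motif <- function(target_seq, pam_seq = "TGG",
                         role = c("forward_target", "reverse_target",
                                  "nontarget")) {
  role <- match.arg(role)
  target_seq <- toupper(target_seq)
  pam_seq <- toupper(pam_seq)
  if (grepl("[^ACGT]", target_seq) || grepl("[^ACGT]", pam_seq))
    stop("motif sequences must be over the alphabet ACGT")
  if (nchar(pam_seq) != 3L || substr(pam_seq, 2L, 3L) != "GG")
    stop("pam_seq must be a 3-nt NGG motif")
  expected_len <- if (role == "nontarget") 18L else 20L
  if (nchar(target_seq) != expected_len)
    stop(sprintf("target_seq for role '%s' must be %d nt", role,
                 expected_len))
  orientation <- if (role == "reverse_target") "reverse" else "forward"
  motif <- if (orientation == "forward") paste0(target_seq, pam_seq)
           else paste0(pam_seq, target_seq)
  structure(list(target_seq = target_seq, pam_seq = pam_seq,
                 orientation = orientation, role = role, motif = motif),
            class = "target_motif")
}

# 0-based offset of the PAM's centre base from the motif start.
pam_center_within_motif <- function(motif) {
  if (motif$orientation == "forward") nchar(motif$target_seq) + 1L else 1L
}

#' Tile a motif through a backbone window
#'
#' Generates one library member per base-pair position in `window`: the
#' member sequence is the backbone with the `len(motif)` bases starting at
#' that position replaced by the motif. Substitution preserves length, so
#' every member has the backbone's length. The PAM position of each member
#' is recorded as the signed bp offset of the PAM's centre base from the
#' dyad and as the corresponding SHL.
#'
#' @param backbone Backbone DNA string.
#' @param motif A [target_motif()].
#' @param window Integer `c(start, end)`: 0-based half-open range of tiling
#'   start positions.
#' @param frame A [nucleosome_frame()] for the backbone.
#' @param id_prefix Prefix for member ids (default derived from the role).
#' @return A data.frame with one row per member: `member_id`, `role`,
#'   `tile_start`, `pam_center_offset`, `shl`, `sequence`.
#' @export
tile_motif <- function(backbone, motif, window, frame = default_frame(),
                       id_prefix = NULL) {
  stopifnot(inherits(motif, "target_motif"))
  m <- nchar(motif$motif)
  L <- nchar(backbone)
  if (m > L) stop("motif longer than backbone")
  window <- as.integer(window)
  positions <- if (window[2L] > window[1L])
    seq.int(window[1L], window[2L] - 1L) else integer(0)
  bad <- positions[positions < 0L | positions + m > L]
  if (length(bad))
    stop(sprintf("tiling position %d puts the motif outside the backbone [0, %d)",
                 bad[1L], L))
  if (is.null(id_prefix))
    id_prefix <- c(forward_target = "fwd", reverse_target = "rev",
                   nontarget = "non")[[motif$role]]
  seqs <- vapply(positions, function(p) {
    paste0(substr(backbone, 1L, p), motif$motif,
           substr(backbone, p + m + 1L, L))
  }, character(1))
  pam_center <- positions + pam_center_within_motif(motif)
  offset <- pam_center - frame$dyad_offset
  data.frame(
    member_id = sprintf("%s_p%03d", id_prefix, positions),
    role = motif$role,
    tile_start = positions,
    pam_center_offset = offset,
    shl = shl_of_offset(offset, frame),
    sequence = seqs,
    stringsAsFactors = FALSE
  )
}

# Screen: does `seq` share any k-mer with any target (either strand)?
shares_kmer <- function(seq, target_kmers, k) {
  n <- nchar(seq)
  if (n < k) return(FALSE)
  kmers <- substring(seq, 1:(n - k + 1L), k:n)
  any(kmers %in% target_kmers)
}

all_kmers <- function(seqs, k) {
  unique(unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    fwd <- substring(s, 1:(n - k + 1L), k:n)
    rc <- revcomp(s)
    c(fwd, substring(rc, 1:(n - k + 1L), k:n))
  })))
}

#' Assemble a tiled nucleosome library
#'
#' Combines the tilings of the configured motifs with exactly one control
#' member (the unmodified native Widom 601 backbone) and a configurable
#' number of nonspecific background filler sequences. Fillers are random
#' sequences with approximately the backbone's GC content, screened so that
#' they share no 17-nt window (either strand) with any configured target
#' sequence — this is what lets them serve as the nonspecific background
#' for Z-score normalisation.
#'
#' @param motifs List of [target_motif()] objects (may be empty).
#' @param window Tiling start window, 0-based half-open; default tiles
#'   from the first position whose motif overlaps the core, through the
#'   core and into the linker, up to the last position that leaves the
#'   3' amplification arm intact (the PAM centre then reaches well past
#'   the nucleosome edge, around SHL 9).
#' @param backbone Backbone string (default [default_backbone()]).
#' @param frame Coordinate frame (default matches the default backbone).
#' @param n_background Number of background filler members (default 50).
#'   Fillers keep the backbone's terminal `primer_arm` bases (every member
#'   of an amplicon library shares the amplification arms) around a
#'   random interior with the backbone's GC content.
#' @param primer_arm Length of the terminal amplification-primer arms
#'   kept constant across members (default 20 bp).
#' @param seed RNG seed for the fillers (mandatory for reproducibility).
#' @param screen_k Filler screening k-mer size (default 17).
#' @param on_duplicate What to do when two tiling positions yield the
#'   identical full sequence (possible when the backbone happens to read
#'   the PAM next to a tiling window): `"drop"` (default) keeps the first
#'   occurrence and records the dropped ids in attribute `dropped`, since
#'   identical sequences cannot be told apart by identity matching;
#'   `"error"` aborts listing the colliding ids.
#' @return A `nuc_library` object: list with `members` (data.frame
#'   `member_id`, `role`, `tile_start`, `pam_center_offset`, `shl`,
#'   `sequence`), `backbone`, `frame`.
#' @export
build_library <- function(motifs = default_motifs(), window = NULL,
                          backbone = default_backbone(),
                          frame = NULL, n_background = 50L,
                          primer_arm = 20L, seed = 1L,
                          screen_k = 17L,
                          on_duplicate = c("drop", "error")) {
  on_duplicate <- match.arg(on_duplicate)
  primer_arm <- as.integer(primer_arm)
  if (is.null(frame)) {
    dyad <- attr(backbone, "dyad_offset")
    frame <- if (is.null(dyad)) default_frame()
             else nucleosome_frame(dyad, backbone_length = nchar(backbone))
  }
  backbone <- as.character(backbone)
  L <- nchar(backbone)
  tiles <- lapply(motifs, function(mo) {
    m <- nchar(mo$motif)
    w <- if (is.null(window))
      c(max(primer_arm, core_limits(frame)[1L] - m + 1L),
        L - primer_arm - m + 1L)
    else window
    tile_motif(backbone, mo, w, frame)
  })
  control <- data.frame(member_id = "control", role = "control",
                        tile_start = NA_integer_,
                        pam_center_offset = NA_integer_, shl = NA_real_,
                        sequence = backbone, stringsAsFactors = FALSE)
  target_kmers <- all_kmers(vapply(motifs, `[[`, character(1), "target_seq"),
                            screen_k)
  gc <- mean(strsplit(backbone, "")[[1]] %in% c("G", "C"))
  set.seed(as.integer(seed))
  arm5 <- substr(backbone, 1L, primer_arm)
  arm3 <- substr(backbone, L - primer_arm + 1L, L)
  n_inner <- L - 2L * primer_arm
  fillers <- character(n_background)
  i <- 1L
  while (i <= n_background) {
    inner <- paste(sample(c("A", "C", "G", "T"), n_inner, replace = TRUE,
                          prob = c((1 - gc) / 2, gc / 2, gc / 2,
                                   (1 - gc) / 2)),
                   collapse = "")
    cand <- paste0(arm5, inner, arm3)
    if (!shares_kmer(cand, target_kmers, screen_k)) {
      fillers[i] <- cand
      i <- i + 1L
    }
  }
  bg <- if (n_background > 0L)
    data.frame(member_id = sprintf("bg_%03d", seq_len(n_background)),
               role = "background", tile_start = NA_integer_,
               pam_center_offset = NA_integer_, shl = NA_real_,
               sequence = fillers, stringsAsFactors = FALSE)
  else control[0L, ]
  members <- rbind(do.call(rbind, c(tiles, list(control[0L, ]))), control, bg)
  rownames(members) <- NULL
  dup <- duplicated(members$sequence)
  dropped <- character(0)
  if (any(dup)) {
    colliding <- members$member_id[members$sequence %in%
                                   members$sequence[dup]]
    if (on_duplicate == "error")
      stop("duplicate member sequences: ",
           paste(colliding, collapse = ", "))
    dropped <- members$member_id[dup]
    members <- members[!dup, , drop = FALSE]
    rownames(members) <- NULL
  }
  stopifnot(!anyDuplicated(members$member_id))
  structure(list(members = members, backbone = backbone, frame = frame),
            class = "nuc_library", dropped = dropped)
}

#' Default target motifs
#'
#' One 20-nt forward target (PAM 3' of target), the same 20-nt sequence in
#' the reverse conformation (PAM 5' of target), and an 18-nt nontarget.
#' All use a TGG PAM so that the tiling differences between conformations
#' are purely positional.
#'
#' @return List of three [target_motif()] objects.
#' @export
default_motifs <- function() {
  list(
    target_motif("GTCACCTACGGATTCAGCAC", "TGG", "forward_target"),
    target_motif("GTCACCTACGGATTCAGCAC", "TGG", "reverse_target"),
    target_motif("ACGTTCGAACCTGATCGA", "TGG", "nontarget")
  )
}

#' @export
print.nuc_library <- function(x, ...) {
  tab <- table(x$members$role)
  cat(sprintf("<nuc_library> %d members (%d bp backbone): %s\n",
              nrow(x$members), nchar(x$backbone),
              paste(sprintf("%s=%d", names(tab), tab), collapse = ", ")))
  invisible(x)
}

#' Look up library members
#' @param library A `nuc_library`.
#' @param role Optional role filter.
#' @return The members data.frame (filtered).
#' @export
library_members <- function(library, role = NULL) {
  m <- library$members
  if (!is.null(role)) m <- m[m$role %in% role, , drop = FALSE]
  m
}

header_of_member <- function(m) {
  sprintf("%s|role=%s|tile_start=%s|pam_center_offset=%s|shl=%s",
          m$member_id, m$role,
          ifelse(is.na(m$tile_start), "NA", m$tile_start),
          ifelse(is.na(m$pam_center_offset), "NA", m$pam_center_offset),
          ifelse(is.na(m$shl), "NA", format(m$shl, trim = TRUE)))
}

parse_header <- function(h, record) {
  parts <- strsplit(h, "|", fixed = TRUE)[[1]]
  kv <- parts[-1]
  keys <- sub("=.*$", "", kv)
  vals <- sub("^[^=]*=", "", kv)
  need <- c("role", "tile_start", "pam_center_offset", "shl")
  if (length(parts) < 2L || !all(need %in% keys))
    stop(sprintf("malformed library FASTA header at record %d: '%s'",
                 record, h))
  v <- stats::setNames(vals, keys)
  list(member_id = parts[1L], role = v[["role"]],
       tile_start = suppressWarnings(as.integer(v[["tile_start"]])),
       pam_center_offset = suppressWarnings(as.integer(v[["pam_center_offset"]])),
       shl = suppressWarnings(as.numeric(v[["shl"]])))
}

#' Write a library to FASTA (metadata in headers)
#'
#' Member metadata is serialised into the header line as `|key=value`
#' pairs so that [read_library_fasta()] round-trips the full design.
#'
#' @param library A `nuc_library`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(library, path) {
  m <- library$members
  seqs <- Biostrings::DNAStringSet(m$sequence)
  names(seqs) <- header_of_member(m)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

#' Read a library written by [write_library_fasta()]
#'
#' @param path FASTA path.
#' @param frame Coordinate frame to attach (default [default_frame()]).
#' @return A `nuc_library`. The backbone is taken from the control member
#'   if present, otherwise left `NA`.
#' @export
read_library_fasta <- function(path, frame = default_frame()) {
  seqs <- Biostrings::readDNAStringSet(path)
  meta <- lapply(seq_along(seqs), function(i)
    parse_header(names(seqs)[i], i))
  members <- data.frame(
    member_id = vapply(meta, `[[`, character(1), "member_id"),
    role = vapply(meta, `[[`, character(1), "role"),
    tile_start = vapply(meta, `[[`, integer(1), "tile_start"),
    pam_center_offset = vapply(meta, `[[`, integer(1), "pam_center_offset"),
    shl = vapply(meta, `[[`, numeric(1), "shl"),
    sequence = as.character(seqs),
    stringsAsFactors = FALSE
  )
  rownames(members) <- NULL
  backbone <- members$sequence[members$role == "control"][1]
  if (is.na(backbone)) backbone <- NA_character_
  structure(list(members = members, backbone = backbone, frame = frame),
            class = "nuc_library")
}

#' Write the library manifest (TSV)
#'
#' @param library A `nuc_library`.
#' @param path Output TSV path.
#' @return `path`, invisibly.
#' @export
write_library_manifest <- function(library, path) {
  utils::write.table(
    library$members[, c("member_id", "role", "tile_start",
                        "pam_center_offset", "shl")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Reverse complement of a DNA string
#' @param seq DNA string(s).
#' @return Reverse complement string(s).
#' @export
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(seq)))
}
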