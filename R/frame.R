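#' Canonical Widom 601 nucleosome-positioning core
#'
#' The 147-bp Widom 601 core sequence, the strongest known synthetic
#' nucleosome-positioning element and the backbone every library member is
#' built on. The dyad is the central base (74th, 0-based offset 73 within
#' this string).
#'
#' @return A single character string of 147 ACGT letters.
#' @export
#' @examples
#' nchar(widom601_core())  # 147
widom601_core <- function() {
  paste0(
    "ATCGGATGTATATATCTGACACGTGCCTGGAGACTAGGGAGTAATCCCCTTGGCGGTTAAAACGCGGG",
    "GGACAGCGCGTACGTGCGTTTAAGCGGTGCTAGAGCTGTCTACGACCAATTGAGCGGCCTCGGCACCG",
    "GGATTCTCCAG"
  )
}

#' Default 230-bp library backbone
#'
#' The 147-bp Widom 601 core flanked by fixed linker sequences to a total
#' construct length of 230 bp (41 bp upstream, 42 bp downstream). The
#' flanks are deterministic: they are generated once from a fixed internal
#' seed with the same GC content as the core, so every call returns the
#' identical sequence.
#'
#' @param total_length Total construct length in bp (default 230).
#' @return A character string of length `total_length` containing the 601
#'   core, with attributes `core_start` (0-based start of the core) and
#'   `dyad_offset` (0-based index of the dyad base).
#' @export
default_backbone <- function(total_length = 230L) {
  core <- widom601_core()
  n_core <- nchar(core)
  stopifnot(total_length >= n_core)
  n_flank <- total_length - n_core
  left <- n_flank %/% 2L
  right <- n_flank - left
  gc <- mean(strsplit(core, "")[[1]] %in% c("G", "C"))
  rng <- local({
    set.seed(601L)
    function(n) {
      sample(c("A", "C", "G", "T"), n, replace = TRUE,
             prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2))
    }
  })
  seq <- paste0(paste(rng(left), collapse = ""), core,
                paste(rng(right), collapse = ""))
  structure(seq,
            core_start = left,
            dyad_offset = left + (n_core - 1L) %/% 2L)
}

#' Nucleosome coordinate frame
#'
#' The coordinate system every profile is indexed by: positions are
#' measured in bp relative to the dyad (the central base of the 147-bp
#' wrap), and in superhelical locations (SHLs) at 10 bp per SHL, negative
#' upstream and positive downstream of the dyad (SHL 0).
#'
#' @param dyad_offset 0-based index of the dyad base within the backbone.
#' @param core_span Length of the nucleosome-forming region in bp
#'   (default 147); must be odd so the core is centred on the dyad.
#' @param bp_per_shl Base pairs per superhelical location (default 10).
#' @param backbone_length Length of the backbone the frame indexes into;
#'   used only to validate `dyad_offset`.
#' @return An object of class `nucleosome_frame`.
#' @export
nucleosome_frame <- function(dyad_offset, core_span = 147L, bp_per_shl = 10L,
                             backbone_length = NULL) {
  dyad_offset <- as.integer(dyad_offset)
  core_span <- as.integer(core_span)
  bp_per_shl <- as.integer(bp_per_shl)
  if (bp_per_shl <= 0L) stop("bp_per_shl must be positive")
  if (core_span %% 2L != 1L)
    stop("core_span must be odd so the core is centred on the dyad")
  if (!is.null(backbone_length) &&
      (dyad_offset < 0L || dyad_offset >= backbone_length))
    stop("dyad_offset outside backbone bounds")
  structure(list(dyad_offset = dyad_offset, core_span = core_span,
                 bp_per_shl = bp_per_shl),
            class = "nucleosome_frame")
}

#' Default frame for the shipped 230-bp backbone
#' @return A `nucleosome_frame` with the dyad at the centre of the 601 core.
#' @export
default_frame <- function() {
  bb <- default_backbone()
  nucleosome_frame(attr(bb, "dyad_offset"), backbone_length = nchar(bb))
}

#' @export
print.nucleosome_frame <- function(x, ...) {
  half <- (x$core_span - 1L) %/% 2L
  cat(sprintf(
    "<nucleosome_frame> dyad at offset %d, %d-bp core (dyad %s %d), %d bp/SHL\n",
    x$dyad_offset, x$core_span, "±", half, x$bp_per_shl))
  invisible(x)
}

#' Convert a dyad-relative offset to an SHL coordinate
#'
#' SHLs occur at `bp_per_shl` (10 bp) intervals from the dyad, negative
#' upstream and positive downstream; the dyad itself is SHL 0.
#'
#' @param offset_bp Signed integer offset(s) in bp from the dyad.
#' @param frame A [nucleosome_frame()].
#' @return Signed decimal SHL value(s).
#' @seealso [offset_of_shl()] for the inverse.
#' @export
#' @examples
#' shl_of_offset(70, default_frame())   # 7
#' shl_of_offset(-66, default_frame())  # -6.6
shl_of_offset <- function(offset_bp, frame = default_frame()) {
  stopifnot(inherits(frame, "nucleosome_frame"))
  offset_bp / frame$bp_per_shl
}

#' Convert an SHL coordinate to a dyad-relative bp offset
#'
#' Inverse of [shl_of_offset()]; round-trips exactly for any offset that is
#' a whole number of base pairs.
#'
#' @param shl Signed decimal SHL value(s).
#' @param frame A [nucleosome_frame()].
#' @return Signed bp offset(s) from the dyad.
#' @export
offset_of_shl <- function(shl, frame = default_frame()) {
  stopifnot(inherits(frame, "nucleosome_frame"))
  shl * frame$bp_per_shl
}

#' Nucleosome core limits of a frame
#'
#' @param frame A [nucleosome_frame()].
#' @return Integer vector `c(start, end)`: 0-based half-open backbone
#'   interval occupied by the nucleosome-forming core.
#' @export
core_limits <- function(frame) {
  half <- (frame$core_span - 1L) %/% 2L
  c(start = frame$dyad_offset - half, end = frame$dyad_offset + half + 1L)
}
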