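# Independent oracles and small fixtures used across the suite.
# Every oracle here is written from the operation's definition, not from
# the implementation's code path.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

rc <- function(s) {
  map <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  paste(rev(unname(map[chars(s)])), collapse = "")
}

random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# --- merge oracle: exhaustive enumeration of every overlap offset -------
merge_oracle <- function(r1, r2, min_overlap = 20L, max_diffs = 2L) {
  n1 <- nchar(r1$seq)
  n2 <- nchar(r2$seq)
  if (n1 == 0L || n2 == 0L) return(list(merged = FALSE, reason = "no_overlap"))
  b <- chars(rc(r2$seq))
  q2 <- rev(r2$qual)
  a <- chars(r1$seq)
  cand_o <- integer(0)
  cand_d <- integer(0)
  for (o in seq_len(min(n1, n2))) {
    d <- sum(a[(n1 - o + 1):n1] != b[1:o])
    if (d <= max_diffs) {
      cand_o <- c(cand_o, o)
      cand_d <- c(cand_d, d)
    }
  }
  if (!length(cand_o)) return(list(merged = FALSE, reason = "too_many_diffs"))
  best <- which.max(cand_o)
  o <- cand_o[best]
  if (o < min_overlap)
    return(list(merged = FALSE, reason = "too_short_overlap"))
  cons <- character(o)
  qc <- integer(o)
  for (k in seq_len(o)) {
    ca <- a[n1 - o + k]; cb <- b[k]
    qa <- r1$qual[n1 - o + k]; qb <- q2[k]
    if (ca == cb) { cons[k] <- ca; qc[k] <- max(qa, qb) }
    else if (qa > qb) { cons[k] <- ca; qc[k] <- qa }
    else if (qb > qa) { cons[k] <- cb; qc[k] <- qb }
    else { cons[k] <- "N"; qc[k] <- 2L }
  }
  list(merged = TRUE,
       seq = paste0(substr(r1$seq, 1, n1 - o), paste(cons, collapse = ""),
                    if (o < n2) substr(rc(r2$seq), o + 1, n2) else ""),
       qual = c(r1$qual[seq_len(n1 - o)], qc,
                if (o < n2) q2[(o + 1):n2] else integer(0)),
       overlap_len = o, n_diffs = cand_d[best])
}

# --- matcher oracle: full DP semiglobal alignment per member ------------
# Global in the read, member prefix/suffix free. Scoring mirrors the
# matcher's contract: match +1, mismatch -2, gap -2 per gapped column.
# Traceback prefers diagonal, then member-gap, then read-gap; test cases
# are substitution-only so the optimum is unique and the preference is
# immaterial.
dp_semiglobal <- function(read, member) {
  r <- chars(read); m <- chars(member)
  N <- length(r); M <- length(m)
  F <- matrix(-Inf, M + 1L, N + 1L)
  F[, 1L] <- 0
  F[1L, ] <- -2 * (0:N)
  for (i in 2:(M + 1L)) {
    sub <- ifelse(m[i - 1L] == r, 1, -2)
    for (j in 2:(N + 1L)) {
      F[i, j] <- max(F[i - 1L, j - 1L] + sub[j - 1L],
                     F[i - 1L, j] - 2, F[i, j - 1L] - 2)
    }
  }
  i <- which.max(F[, N + 1L])
  score <- F[i, N + 1L]
  j <- N + 1L
  matches <- 0L; cols <- 0L
  while (j > 1L) {
    if (i > 1L && F[i, j] == F[i - 1L, j - 1L] +
          (if (m[i - 1L] == r[j - 1L]) 1 else -2)) {
      matches <- matches + (m[i - 1L] == r[j - 1L])
      cols <- cols + 1L; i <- i - 1L; j <- j - 1L
    } else if (i > 1L && F[i, j] == F[i - 1L, j] - 2) {
      cols <- cols + 1L; i <- i - 1L
    } else {
      cols <- cols + 1L; j <- j - 1L
    }
  }
  list(score = score, identity = matches / cols, cols = cols)
}

match_oracle <- function(read, library, min_identity = 0.985,
                         min_cols = 150L) {
  st <- lapply(library$members$sequence, function(mem)
    dp_semiglobal(read, mem))
  ident <- vapply(st, `[[`, numeric(1), "identity")
  best <- max(ident)
  hits <- which(ident >= best - 1e-12)
  if (length(hits) > 1L) return(list(status = "ambiguous"))
  colsb <- st[[hits]]$cols
  status <- if (colsb < min_cols) "too_short_alignment"
            else if (best < min_identity) "low_identity" else "assigned"
  list(status = status,
       member_id = if (status == "assigned")
         library$members$member_id[hits] else NA_character_,
       identity = best, cols = colsb)
}

# --- clash oracle: O(n^2) pair enumeration ------------------------------
clash_oracle <- function(a, b, overlap_cutoff = 0.6) {
  A <- as.matrix(a[, c("x", "y", "z")])
  B <- as.matrix(b[, c("x", "y", "z")])
  total <- 0L
  for (i in seq_len(nrow(A))) {
    d <- sqrt((B[, 1] - A[i, 1])^2 + (B[, 2] - A[i, 2])^2 +
              (B[, 3] - A[i, 3])^2)
    total <- total + sum(a$radius[i] + b$radius - d >= overlap_cutoff)
  }
  as.integer(total)
}

# --- coverage oracle: per-bp membership test ----------------------------
coverage_oracle <- function(fragments, member_len) {
  vapply(seq_len(member_len) - 1L, function(bp)
    sum(fragments$start <= bp & bp < fragments$end), integer(1))
}

# --- fixtures -----------------------------------------------------------
# 20-member toy library: 4 well-separated reverse-target tiles, the
# control, and 15 background fillers.
toy_library <- function() {
  lib <- build_library(n_background = 16L, seed = 3L)
  rev_ids <- library_members(lib, "reverse_target")$member_id
  keep <- c(rev_ids[c(1, 40, 80, 120)], "control",
            library_members(lib, "background")$member_id[1:15])
  lib$members <- lib$members[lib$members$member_id %in% keep, ,
                             drop = FALSE]
  rownames(lib$members) <- NULL
  lib
}

# helix-like synthetic DNA chain of P atoms, one per residue
helix_chain <- function(letters, chain, jitter = 0) {
  n <- length(letters)
  t <- seq_len(n)
  atom_set(x = cos(t / 2) * 10 + stats::rnorm(n, 0, jitter),
           y = sin(t / 2) * 10 + stats::rnorm(n, 0, jitter),
           z = t * 3.4 + stats::rnorm(n, 0, jitter),
           element = "P", chain = chain, resno = t,
           resid = paste0("D", letters), atom_name = "P")
}
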