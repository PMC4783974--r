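#' Seed-and-extend ortholog scan
#'
#' A deliberately small, fully documented local aligner used to match
#' candidate transcripts against reference sequences at fixture scale:
#' exact k-mer seeds, ungapped extension scored +1 per match and -2 per
#' mismatch with an X-drop of `xdrop`, one extension per alignment
#' diagonal.  Hits must reach `min_identity` over at least
#' `min_aligned_len` aligned bases; the best-scoring hit per query is
#' flagged.  Both query strands are scanned; reference coordinates are
#' always on the forward strand.
#'
#' This is a stand-in for a full local aligner such as BLAST, adequate at
#' synthetic scale; precomputed hit tables in the same shape can be passed
#' to [place_gene()] instead.
#'
#' @param queries,references Named character vectors of uppercase DNA.
#' @param k Seed length.
#' @param min_identity Minimum identity fraction in `[0, 1]`.
#' @param min_aligned_len Minimum aligned length in bp.
#' @param xdrop Score drop at which extension stops.
#' @return Tibble: `query`, `reference`, `strand`, `score`, `identity`,
#'   `aligned_len`, `q_start`, `q_end`, `r_start`, `r_end`, `best`
#'   (logical, best hit per query).
#' @export
#' @examples
#' refs <- c(g1 = paste(rep("ACGTTGCA", 30), collapse = ""))
#' scan_orthologs(c(q = substr(refs[[1]], 20, 150)), refs,
#'                min_aligned_len = 50)
scan_orthologs <- function(queries, references, k = 11L,
                           min_identity = 0.9, min_aligned_len = 100L,
                           xdrop = 20L) {
  if (any(nchar(c(queries, references)) < k)) {
    stop_arg("`k` = ", k, " exceeds the length of an input sequence")
  }
  ref_chars <- lapply(references, function(s) strsplit(s, "")[[1]])
  ref_index <- lapply(references, function(s) {
    n <- nchar(s) - k + 1L
    kmers <- substring(s, seq_len(n), seq_len(n) + k - 1L)
    split(seq_len(n), kmers)
  })

  hits <- list()
  for (qname in names(queries)) {
    for (strand in c("+", "-")) {
      qseq <- if (strand == "+") queries[[qname]] else revcomp(queries[[qname]])
      qc <- strsplit(qseq, "")[[1]]
      nq <- length(qc) - k + 1L
      if (nq < 1L) next
      qkmers <- substring(qseq, seq_len(nq), seq_len(nq) + k - 1L)
      for (rname in names(references)) {
        idx <- ref_index[[rname]]
        rc <- ref_chars[[rname]]
        seen <- integer(0)
        best_hit <- NULL
        qpos_list <- which(qkmers %in% names(idx))
        for (qpos in qpos_list) {
          for (rpos in idx[[qkmers[qpos]]]) {
            diag <- rpos - qpos
            if (diag %in% seen) next
            seen <- c(seen, diag)
            h <- extend_seed(qc, rc, qpos, rpos, k, xdrop)
            if (is.null(best_hit) || h$score > best_hit$score) best_hit <- h
          }
        }
        if (is.null(best_hit)) next
        if (best_hit$identity >= min_identity &&
            best_hit$aligned_len >= min_aligned_len) {
          hits[[length(hits) + 1L]] <- tibble(
            query = qname, reference = rname, strand = strand,
            score = best_hit$score, identity = best_hit$identity,
            aligned_len = best_hit$aligned_len,
            q_start = best_hit$q_start, q_end = best_hit$q_end,
            r_start = best_hit$r_start, r_end = best_hit$r_end)
        }
      }
    }
  }
  out <- bind_rows(hits)
  if (nrow(out) == 0L) {
    return(tibble(query = character(), reference = character(),
                  strand = character(), score = integer(),
                  identity = double(), aligned_len = integer(),
                  q_start = integer(), q_end = integer(),
                  r_start = integer(), r_end = integer(), best = logical()))
  }
  out |>
    group_by(.data$query) |>
    mutate(best = seq_len(n()) == which.max(.data$score)) |>
    ungroup()
}

# Ungapped extension of an exact k-mer seed in both directions.
# Match +1, mismatch -2; stops when the running score drops `xdrop`
# below the best seen; returns the best-scoring segment.
extend_seed <- function(qc, rc, qpos, rpos, k, xdrop) {
  score <- k; best <- k
  ql <- qpos; rl <- rpos; best_ql <- qpos; best_rl <- rpos
  i <- qpos - 1L; j <- rpos - 1L
  while (i >= 1L && j >= 1L) {
    score <- score + if (qc[i] == rc[j]) 1L else -2L
    if (score > best) { best <- score; best_ql <- i; best_rl <- j }
    if (score < best - xdrop) break
    i <- i - 1L; j <- j - 1L
  }
  score <- best
  qr <- qpos + k - 1L; rr <- rpos + k - 1L
  best_qr <- qr; best_rr <- rr
  i <- qr + 1L; j <- rr + 1L
  while (i <= length(qc) && j <= length(rc)) {
    score <- score + if (qc[i] == rc[j]) 1L else -2L
    if (score > best) { best <- score; best_qr <- i; best_rr <- j }
    if (score < best - xdrop) break
    i <- i + 1L; j <- j + 1L
  }
  len <- best_qr - best_ql + 1L
  matches <- sum(qc[best_ql:best_qr] == rc[best_rl:best_rr])
  list(score = best, q_start = best_ql, q_end = best_qr,
       r_start = best_rl, r_end = best_rr,
       aligned_len = len, identity = matches / len)
}

#' Place a transcript on the genome
#'
#' Returns a placement only when exactly one scaffold carries a passing
#' hit; hits on several scaffolds are ambiguous and yield no placement.
#'
#' @param transcript Named character vector of length 1 (or a bare string,
#'   then named `"query"`).
#' @param scaffolds Named character vector of scaffold sequences.
#' @param hits Optional precomputed hit table in [scan_orthologs()] shape;
#'   when supplied the scan is skipped.
#' @inheritParams scan_orthologs
#' @return One-row tibble `query`, `scaffold`, `start`, `end`, `strand`,
#'   `identity`, `placed`, `reason` (`NA`, `"no hit"` or `"non-unique"`).
#' @export
place_gene <- function(transcript, scaffolds, k = 11L, min_identity = 0.9,
                       min_aligned_len = 100L, hits = NULL) {
  if (is.null(names(transcript))) names(transcript) <- "query"
  if (is.null(hits)) {
    hits <- scan_orthologs(transcript, scaffolds, k = k,
                           min_identity = min_identity,
                           min_aligned_len = min_aligned_len)
  }
  qname <- names(transcript)[1]
  none <- function(reason) {
    tibble(query = qname, scaffold = NA_character_, start = NA_integer_,
           end = NA_integer_, strand = NA_character_, identity = NA_real_,
           placed = FALSE, reason = reason)
  }
  hits <- filter(hits, .data$query == qname)
  if (nrow(hits) == 0L) return(none("no hit"))
  if (length(unique(hits$reference)) > 1L) return(none("non-unique"))
  top <- hits[which.max(hits$score), ]
  tibble(query = qname, scaffold = top$reference, start = top$r_start,
         end = top$r_end, strand = top$strand, identity = top$identity,
         placed = TRUE, reason = NA_character_)
}
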