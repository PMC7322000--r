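# Independent brute-force oracles. These deliberately share no code with the
# implementation: plain per-fragment loops and direct formula evaluation.

oracle_count <- function(fragments, annotation, level, mode) {
  iv <- annotation$intervals
  lens <- unit_lengths(annotation, level)
  counts <- stats::setNames(numeric(length(lens)), names(lens))
  unassigned <- 0
  for (i in seq_len(nrow(fragments))) {
    fs <- fragments$start[i]; fe <- fragments$end[i]
    ct <- fragments$contig[i]
    if (mode == "midpoint") {
      mid <- fs + floor((fe - fs) / 2)
      cand <- which(iv$contig == ct & iv$start <= mid & iv$end > mid)
      if (length(cand) == 0L) { unassigned <- unassigned + 1; next }
      cand <- cand[order(iv$start[cand], iv$instance_id[cand])][1]
      counts[iv[[level]][cand]] <- counts[iv[[level]][cand]] + 1
    } else {
      ov <- pmin(fe, iv$end) - pmax(fs, iv$start)
      ov[iv$contig != ct] <- 0
      cand <- which(ov > 0)
      if (length(cand) == 0L) { unassigned <- unassigned + 1; next }
      if (mode == "any_overlap") {
        cand <- cand[order(-ov[cand], iv$start[cand], iv$instance_id[cand])][1]
        counts[iv[[level]][cand]] <- counts[iv[[level]][cand]] + 1
      } else {
        w <- ov[cand] / (fe - fs)
        if (sum(w) > 1) w <- w / sum(w)
        for (k in seq_along(cand)) {
          u <- iv[[level]][cand[k]]
          counts[u] <- counts[u] + w[k]
        }
        unassigned <- unassigned + (1 - sum(w))
      }
    }
  }
  list(counts = counts, unassigned = unassigned)
}

oracle_dedup <- function(fragments) {
  df <- as.data.frame(fragments)
  df <- df[order(df$contig, df$start, df$end), , drop = FALSE]
  key <- paste(df$contig, df$start, df$strand)
  keep <- !duplicated(key)
  out <- df[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_fpkm <- function(count, unit_length, library_size) {
  count * 1e9 / (unit_length * library_size)
}

oracle_filter <- function(fragments, rrna, mrna) {
  cls <- character(nrow(fragments))
  hits_any <- function(fs, fe, ct, iv) {
    any(iv$contig == ct & iv$start < fe & iv$end > fs)
  }
  for (i in seq_len(nrow(fragments))) {
    fs <- fragments$start[i]; fe <- fragments$end[i]; ct <- fragments$contig[i]
    cls[i] <- if (nrow(rrna) > 0 && hits_any(fs, fe, ct, rrna)) "rrna"
    else if (nrow(mrna) > 0 && hits_any(fs, fe, ct, mrna)) "mrna"
    else "retained"
  }
  cls
}

oracle_screen <- function(table, ref, cmp, c0 = 1, min_shown = 3,
                          hit_min = 6, hit_fold = 2) {
  rows <- lapply(seq_len(nrow(table)), function(i) {
    nr <- table[[ref]][i]; nc <- table[[cmp]][i]
    r <- (nr + c0) / (nc + c0)
    data.frame(protein = table$protein[i], ratio = r,
               shown = max(nr, nc) >= min_shown,
               hit = max(nr, nc) > hit_min && r > hit_fold,
               n_ref = nr, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(-out$ratio, -out$n_ref, out$protein), , drop = FALSE]
}
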