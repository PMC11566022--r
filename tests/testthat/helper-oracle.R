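# Independent brute-force pairing scorer used as the oracle for
# scan equivalence checks.

brute_force_calls <- function(groups, products, transcripts) {
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  rules <- list(R1 = list(min_ppm = 1, win = 2:25, need = 20, contig = FALSE),
                R2 = list(min_ppm = 5, win = 3:15, contig = TRUE),
                R3 = list(min_ppm = 10, win = 3:16, contig = TRUE),
                R4 = list(min_ppm = 50, win = 4:17, contig = TRUE))
  out <- list()
  guide_chars <- lapply(groups$sequence, function(s) strsplit(s, "")[[1]])
  tx_chars <- lapply(transcripts, function(s) strsplit(s, "")[[1]])
  for (p in seq_len(nrow(products))) {
    tx <- tx_chars[[products$transcript_id[p]]]
    pos <- products$position[p]
    for (g in seq_len(nrow(groups))) {
      gch <- guide_chars[[g]]
      match <- logical(30)
      for (k in 1:30) {
        i <- pos + 10 - k + 1
        if (k <= length(gch) && i >= 1 && i <= length(tx))
          match[k] <- comp[[gch[k]]] == tx[i]
      }
      sat <- character(0)
      for (rn in names(rules)) {
        r <- rules[[rn]]
        if (groups$ppm[g] < r$min_ppm) next
        ok <- if (r$contig) all(match[r$win]) else sum(match[r$win]) >= r$need
        if (ok) sat <- c(sat, rn)
      }
      if (length(sat) > 0)
        out[[length(out) + 1]] <- data.frame(
          guide_id = groups$guide_id[g],
          transcript_id = products$transcript_id[p],
          position = pos, rules = paste(sat, collapse = ","),
          stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0)
    return(data.frame(guide_id = character(0), transcript_id = character(0),
                      position = integer(0), rules = character(0)))
  do.call(rbind, out)
}
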