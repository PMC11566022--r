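# Guide:target pairing engine.
#
# Coordinates follow the Argonaute slicing register: the 5'-monophosphate
# nucleotide of the 3' cleavage product (0-based transcript coordinate p)
# pairs guide position g10, i.e. slicing occurs between the target bases
# paired to g10 and g11. Guide position k (k = 1..30, counted from the guide
# 5' end) therefore pairs transcript coordinate p + 10 - k. Positions falling
# outside the transcript, or beyond the guide's own length, are unpaired.

DNA_COMPLEMENT <- c(A = "T", C = "G", G = "C", T = "A")

# uppercase, RNA -> DNA alphabet
normalize_seq <- function(x) {
  chartr("u", "T", chartr("U", "T", toupper(x)))
}

seq_chars <- function(x) strsplit(normalize_seq(x), "", fixed = TRUE)[[1]]

# expected guide base for each target base under Watson-Crick (+ optional
# G.U wobble handled at comparison time)
.wc_match <- function(guide_base, target_base, wobble = FALSE) {
  wc <- DNA_COMPLEMENT[guide_base] == target_base
  if (!wobble) return(wc & !is.na(wc))
  gu <- (guide_base == "G" & target_base == "T") |
    (guide_base == "T" & target_base == "G")
  (wc | gu) & !is.na(wc)
}

#' Align a guide piRNA against a transcript at a cleavage site
#'
#' Evaluates Watson-Crick complementarity between guide positions g1-g30 and
#' the transcript window anchored at a putative cleavage site: guide position
#' k pairs transcript coordinate `position + 10 - k` (0-based). T and U are
#' equivalent. Out-of-range transcript positions and positions beyond the
#' guide length are unpaired, never an error, so sites hanging off transcript
#' ends are evaluated on the overlapping part.
#'
#' @param guide guide sequence (character, RNA or DNA alphabet), 5' to 3'.
#' @param transcript transcript sequence (character or `DNAString`).
#' @param position 0-based coordinate of the 5' nucleotide of the 3'
#'   cleavage product.
#' @param wobble if `TRUE`, G.U wobbles count as paired (default `FALSE`).
#' @return A `pairing_result`: list with `match` (logical, length 30),
#'   `guide` (normalized guide sequence) and `position`.
#' @seealso [paired_in()], [is_contiguous()], [satisfies_tier()]
#' @export
align_guide_at_site <- function(guide, transcript, position, wobble = FALSE) {
  if (is.null(guide) || !nzchar(guide)) stop("empty guide")
  if (position < 0) stop("position must be >= 0")
  g <- seq_chars(guide)
  tx <- seq_chars(as.character(transcript))
  k <- seq_len(30L)
  coord <- position + 10L - k          # 0-based target coordinate per k
  idx <- coord + 1L
  in_tx <- idx >= 1L & idx <= length(tx)
  in_guide <- k <= length(g)
  match <- logical(30L)
  ok <- in_tx & in_guide
  match[ok] <- .wc_match(g[k[ok]], tx[idx[ok]], wobble = wobble)
  structure(
    list(match = match, guide = paste(g, collapse = ""), position = position),
    class = "pairing_result"
  )
}

#' Number of paired guide positions within an inclusive window
#'
#' @param pairing a `pairing_result`.
#' @param ga,gb window bounds as guide positions (inclusive), e.g. 2 and 25.
#' @return integer count of paired positions.
#' @export
paired_in <- function(pairing, ga, gb) {
  stopifnot(ga >= 1, gb <= 30, ga <= gb)
  sum(pairing$match[ga:gb])
}

#' Is a guide-position window fully paired?
#'
#' @inheritParams paired_in
#' @return `TRUE` iff every position in `ga:gb` is paired.
#' @export
is_contiguous <- function(pairing, ga, gb) {
  stopifnot(ga >= 1, gb <= 30, ga <= gb)
  all(pairing$match[ga:gb])
}

#' The abundance-tiered pairing rules
#'
#' Four parallel rules decide whether a piRNA could have directed cleavage at
#' a site, each combining a minimum intracellular abundance with a pairing
#' geometry: R1, >= 1 ppm and >= 20 nt paired anywhere in g2-g25; R2,
#' >= 5 ppm and contiguous pairing g3-g15; R3, >= 10 ppm and contiguous
#' g3-g16; R4, >= 50 ppm and contiguous g4-g17. A pair is callable if any
#' rule holds (rules are combined by OR).
#'
#' @return data frame with columns `rule`, `min_ppm`, `type`
#'   (`"count"`/`"contiguous"`), `ga`, `gb`, `min_paired`.
#' @export
tier_rules <- function() {
  data.frame(
    rule = c("R1", "R2", "R3", "R4"),
    min_ppm = c(1, 5, 10, 50),
    type = c("count", "contiguous", "contiguous", "contiguous"),
    ga = c(2L, 3L, 3L, 4L),
    gb = c(25L, 15L, 16L, 17L),
    min_paired = c(20L, 13L, 14L, 14L),
    stringsAsFactors = FALSE
  )
}

#' Evaluate the tiered pairing rules for one guide:site pair
#'
#' @param pairing a `pairing_result`.
#' @param abundance_ppm the guide's abundance in ppm (>= 0); each rule is
#'   only available when its abundance precondition holds.
#' @param rules rule table, defaults to [tier_rules()].
#' @return list with `satisfied_rules` (character vector, possibly empty)
#'   and `callable` (logical).
#' @export
satisfies_tier <- function(pairing, abundance_ppm, rules = tier_rules()) {
  if (abundance_ppm < 0) stop("abundance must be >= 0")
  sat <- vapply(seq_len(nrow(rules)), function(i) {
    r <- rules[i, ]
    if (abundance_ppm < r$min_ppm) return(FALSE)
    n <- paired_in(pairing, r$ga, r$gb)
    if (r$type == "contiguous") n == (r$gb - r$ga + 1L) else n >= r$min_paired
  }, logical(1))
  list(satisfied_rules = rules$rule[sat], callable = any(sat))
}

# Watson-Crick RNA/RNA nearest-neighbor stack free energies (delta-G37,
# kcal/mol; Xia et al. 1998 / Turner 2004 parameters). Keyed by the guide
# 5'->3' dinucleotide; the antiparallel complement is implied. A stack and
# its reverse-complement share one value.
NN_STACK_DG <- c(
  AA = -0.93, UU = -0.93,
  AU = -1.10,
  UA = -1.33,
  AC = -2.24, GU = -2.24,
  AG = -2.08, CU = -2.08,
  CA = -2.11, UG = -2.11,
  GA = -2.35, UC = -2.35,
  CG = -2.36,
  GC = -3.42,
  GG = -3.26, CC = -3.26
)

#' Predicted duplex free energy of the paired positions
#'
#' Nearest-neighbor stack sum over runs of consecutively paired guide
#' positions, using Watson-Crick RNA/RNA stacking parameters. Annotation
#' only: the value is reported alongside target calls but never used to
#' decide callability. No initiation or terminal penalties are added, so an
#' alignment with no two adjacent paired positions scores 0.
#'
#' @param pairing a `pairing_result`.
#' @return free energy in kcal/mol (0 when nothing is stacked).
#' @export
duplex_delta_G <- function(pairing) {
  m <- pairing$match
  g <- seq_chars(pairing$guide)
  g <- chartr("T", "U", g)
  stacked <- which(m[-30] & m[-1])      # k with both k and k+1 paired
  if (length(stacked) == 0L) return(0)
  dinucs <- paste0(g[stacked], g[stacked + 1L])
  sum(NN_STACK_DG[dinucs])
}
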