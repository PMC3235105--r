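#' Binary temporal up-regulation pattern from per-stage calls
#'
#' Binarizes a gene's per-stage differential-expression calls: `"up"` maps to
#' `TRUE`, while `"down"` and `"unchanged"` both map to `FALSE`. The
#' resulting ordered tuple over the five stages is the gene's temporal
#' profile; the 31 non-empty tuples define the combinatorial pattern classes.
#'
#' @param calls Character vector of calls, one per stage, in stage order.
#' @param stages Stage labels (defaults to the canonical five).
#' @return Named logical vector (the pattern), one element per stage.
#' @export
#' @examples
#' pattern_of(c("down", "up", "unchanged", "up", "down"))
pattern_of <- function(calls, stages = limb_stages()) {
  if (length(calls) != length(stages)) {
    stop("need exactly one call per stage (", length(stages), ")")
  }
  bad <- setdiff(unique(calls), c("up", "down", "unchanged"))
  if (length(bad)) stop("unknown call value(s): ", paste(bad, collapse = ", "))
  setNames(calls == "up", stages)
}

#' @noRd
as_pattern_logical <- function(pattern) {
  if (is.character(pattern)) {
    stopifnot(length(pattern) == 1L)
    as.integer(strsplit(pattern, "")[[1]]) == 1L
  } else {
    as.logical(pattern)
  }
}

#' Pattern bitstring and class id
#'
#' Patterns are written as bitstrings in stage order (e.g. `"01100"` = up at
#' E10.5 and E11.5 only). The class id of a non-empty pattern is the value of
#' its bitstring read as a binary number (1-31), a fixed bijection between
#' ids and patterns.
#'
#' @param pattern Logical vector or bitstring.
#' @return `pattern_string()`: the bitstring; `pattern_class_id()`: integer
#'   class id in 1-31 (`NA` for the empty pattern).
#' @export
pattern_string <- function(pattern) {
  paste(as.integer(as_pattern_logical(pattern)), collapse = "")
}

#' @rdname pattern_string
#' @export
pattern_class_id <- function(pattern) {
  id <- strtoi(pattern_string(pattern), base = 2L)
  if (id == 0L) NA_integer_ else id
}

#' Categorize a temporal pattern
#'
#' Non-empty patterns fall into five disjoint categories: `"stage-specific"`
#' (up at exactly one stage), `"early"` (a contiguous run of >= 2 up-stages
#' starting at the first stage), `"late"` (a contiguous run of >= 2
#' up-stages ending at the last stage but not starting at the first),
#' `"peak"` (a contiguous internal run of >= 2 up-stages touching neither
#' end), and `"oscillating"` (any non-contiguous set of up-stages). Over the
#' 31 non-empty five-stage patterns the census is 5/4/3/3/16 respectively.
#'
#' @param pattern Logical vector or bitstring; must be non-empty (>= 1 up).
#' @return One of `"stage-specific"`, `"early"`, `"late"`, `"peak"`,
#'   `"oscillating"`.
#' @export
#' @examples
#' categorize_pattern("01100")  # peak
#' categorize_pattern("01111")  # late
#' categorize_pattern("10100")  # oscillating
categorize_pattern <- function(pattern) {
  bits <- as_pattern_logical(pattern)
  idx <- which(bits)
  if (!length(idx)) stop("empty pattern has no category")
  if (length(idx) == 1L) return("stage-specific")
  if (any(diff(idx) != 1L)) return("oscillating")
  if (idx[1] == 1L) return("early")
  if (idx[length(idx)] == length(bits)) return("late")
  "peak"
}

#' Census of the 31 pattern classes by category
#'
#' Enumerates all non-empty five-stage patterns and counts them per
#' category. The partition is invariant: 5 stage-specific, 4 early, 3 late,
#' 3 peak, 16 oscillating.
#'
#' @return Named integer vector of counts per category (summing to 31).
#' @export
class_census <- function() {
  pats <- all_pattern_strings()
  cats <- vapply(pats, categorize_pattern, character(1))
  counts <- table(factor(cats, levels = c("stage-specific", "early", "late",
                                          "peak", "oscillating")))
  setNames(as.integer(counts), names(counts))
}

#' Assign temporal profiles to genes from a DE table
#'
#' Collects each gene's limb-versus-control calls across the stages for one
#' limb tissue, binarizes them into a pattern, and keeps the genes that are
#' up-regulated at one or more stages. Every such gene lands in exactly one
#' of the 31 pattern classes and one of the five categories.
#'
#' @param de DE table from [run_all_contrasts()].
#' @param tissue `"forelimb"` (default) or `"hindlimb"`.
#' @return Data frame with columns `gene`, `pattern` (bitstring), `class_id`,
#'   `category`; attribute `"stages"` records the stage order used.
#' @export
assign_profiles <- function(de, tissue = "forelimb") {
  sub <- de[de$type == "limb_vs_we" & de$tissue == tissue, , drop = FALSE]
  if (!nrow(sub)) stop("no limb-vs-control contrasts for tissue ", tissue)
  stages <- intersect(limb_stages(), unique(sub$stage))
  up <- matrix(FALSE, length(unique(sub$gene)), length(stages),
               dimnames = list(sort(unique(sub$gene)), stages))
  for (s in stages) {
    rows <- sub[sub$stage == s, ]
    up[rows$gene, s] <- rows$call == "up"
  }
  any_up <- rowSums(up) > 0
  up <- up[any_up, , drop = FALSE]
  pattern <- apply(up, 1L, function(b) paste(as.integer(b), collapse = ""))
  out <- data.frame(
    gene = rownames(up),
    pattern = unname(pattern),
    class_id = strtoi(pattern, base = 2L),
    category = vapply(pattern, categorize_pattern, character(1), USE.NAMES = FALSE),
    row.names = NULL, stringsAsFactors = FALSE
  )
  attr(out, "stages") <- stages
  out
}

#' Genes up-regulated at exactly one stage
#'
#' @param assignments Profile assignments from [assign_profiles()].
#' @param stage Stage label.
#' @return Character vector of genes whose pattern is up at `stage` only.
#' @export
stage_specific <- function(assignments, stage) {
  stages <- attr(assignments, "stages")
  if (is.null(stages)) stages <- limb_stages()
  pos <- match(stage, stages)
  if (is.na(pos)) stop("unknown stage: ", stage)
  target <- paste(as.integer(seq_along(stages) == pos), collapse = "")
  sort(assignments$gene[assignments$pattern == target])
}

#' Genes exclusively up-regulated at one of two consecutive stages
#'
#' For two successive stages, returns the genes up-regulated at the first
#' stage but down-regulated or unchanged at the second, and vice versa --
#' the stage-transition cohorts compared between pairs of successive time
#' points.
#'
#' @param de DE table from [run_all_contrasts()].
#' @param stage_t,stage_t1 The two consecutive stage labels.
#' @param tissue Limb tissue whose contrasts are used.
#' @return List with character-vector elements `only_t` and `only_t1`.
#' @export
exclusive_between_consecutive <- function(de, stage_t, stage_t1,
                                          tissue = "forelimb") {
  sub <- de[de$type == "limb_vs_we" & de$tissue == tissue, , drop = FALSE]
  up_at <- function(stage) {
    rows <- sub[sub$stage == stage, ]
    if (!nrow(rows)) stop("missing contrast for ", tissue, " at ", stage)
    rows$gene[rows$call == "up"]
  }
  up_t <- up_at(stage_t)
  up_t1 <- up_at(stage_t1)
  list(only_t = sort(setdiff(up_t, up_t1)),
       only_t1 = sort(setdiff(up_t1, up_t)))
}

#' Top up-regulated genes of a contrast, ranked by fold change
#'
#' Genes passing the differential-expression call in the given contrast,
#' sorted by decreasing fold change; ties are broken by increasing adjusted
#' p-value and then by gene id, so the ranking is deterministic.
#'
#' @param de DE table from [run_all_contrasts()].
#' @param contrast Contrast name (e.g. `"FL_E10.5"`).
#' @param n Maximum number of genes to return (> 0); if fewer genes qualify,
#'   all of them are returned.
#' @return Data frame of the ranked rows of the DE table.
#' @export
top_upregulated <- function(de, contrast, n) {
  if (n <= 0) stop("n must be positive")
  rows <- de[de$contrast == contrast & de$call == "up", , drop = FALSE]
  if (!nrow(de[de$contrast == contrast, ])) stop("unknown contrast: ", contrast)
  ord <- order(-rows$fc, rows$adj_p, rows$gene)
  rows <- rows[ord, , drop = FALSE]
  rownames(rows) <- NULL
  utils::head(rows, n)
}
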