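# Jensen-Shannon divergence conservation scoring of alignment columns,
# reference-coordinate mapping, and motif-overlap counting.

#' Amino-acid background distributions
#'
#' `"blosum62"` gives the marginal amino-acid frequencies of the BLOSUM62
#' substitution data (the default background of the standard JSD
#' conservation scorer); `"uniform"` gives 1/20 for every residue.
#'
#' @param name `"blosum62"` or `"uniform"`
#' @return named numeric vector over the 20 amino acids, summing to 1
#' @export
aa_background <- function(name = c("blosum62", "uniform")) {
  name <- match.arg(name)
  if (name == "uniform") {
    return(setNames(rep(1 / 20, 20), AA20))
  }
  bg <- c(A = 0.074, R = 0.052, N = 0.045, D = 0.054, C = 0.025,
          Q = 0.034, E = 0.054, G = 0.074, H = 0.026, I = 0.068,
          L = 0.099, K = 0.058, M = 0.025, F = 0.047, P = 0.039,
          S = 0.057, T = 0.051, W = 0.013, Y = 0.032, V = 0.073)
  bg <- bg[AA20]
  bg / sum(bg)
}

as_alignment <- function(alignment) {
  if (inherits(alignment, "AAStringSet")) {
    alignment <- setNames(as.character(alignment), names(alignment))
  }
  if (!is.character(alignment) || is.null(names(alignment))) {
    abort("alignment must be a named character vector or AAStringSet")
  }
  if (length(unique(nchar(alignment))) != 1L) {
    abort("alignment rows differ in length")
  }
  alignment
}

aln_matrix <- function(alignment) {
  do.call(rbind, strsplit(unname(alignment), ""))
}

#' Residue distribution of one alignment column
#'
#' Frequencies over the 20 amino acids among non-gap residues of the
#' column, optionally pseudocount-smoothed, always normalised to sum to
#' 1. The gap fraction is reported separately. Unknown residues (`X`)
#' are excluded like gaps but do not count toward the gap fraction.
#'
#' @param alignment named gapped strings (or AAStringSet)
#' @param column 1-based column index
#' @param pseudocount added to every residue count before normalising
#' @return list (freq: named 20-vector, gap_fraction)
#' @export
column_distribution <- function(alignment, column, pseudocount = 0) {
  alignment <- as_alignment(alignment)
  len <- nchar(alignment[[1]])
  if (column < 1 || column > len) {
    abort(sprintf("column %d outside alignment of length %d", column, len))
  }
  chars <- substring(alignment, column, column)
  gap_fraction <- mean(chars == "-")
  res <- chars[chars %in% AA20]
  counts <- table(factor(res, levels = AA20))
  tot <- sum(counts) + 20 * pseudocount
  freq <- if (tot > 0) (as.numeric(counts) + pseudocount) / tot else
    rep(0, 20)
  list(freq = setNames(freq, AA20), gap_fraction = gap_fraction)
}

#' Jensen-Shannon divergence between two distributions
#'
#' JSD = lambda KL(p || m) + (1 - lambda) KL(q || m), with
#' m = lambda p + (1 - lambda) q and logarithms base 2. Symmetric at
#' lambda = 0.5 and bounded by 1.
#'
#' @param p,q probability vectors of equal length (sums within 1e-6 of 1)
#' @param lambda mixture weight in (0,1), default 0.5
#' @return divergence in `[0, 1]`
#' @export
js_divergence <- function(p, q, lambda = 0.5) {
  if (length(p) != length(q)) {
    abort("p and q must have equal length")
  }
  if (abs(sum(p) - 1) > 1e-6 || abs(sum(q) - 1) > 1e-6) {
    abort("p and q must each sum to 1")
  }
  if (lambda <= 0 || lambda >= 1) {
    abort("lambda must be in (0, 1)", "septinevo_invalid_parameter")
  }
  m <- lambda * p + (1 - lambda) * q
  kl <- function(a, b) {
    nz <- a > 0
    sum(a[nz] * (log2(a[nz]) - log2(b[nz])))
  }
  lambda * kl(p, m) + (1 - lambda) * kl(q, m)
}

#' Jensen-Shannon conservation profile of an alignment
#'
#' Per-column conservation score
#' `(1 - gap_fraction) * JSD(column distribution, background)`; all-gap
#' columns score 0. A window average in the style of the standard JSD
#' scorer is available: with `window = w > 0` the column keeps weight 0.5
#' and the up-to-`2w` flanking columns share the other 0.5. The default
#' `window = 0` scores each column alone.
#'
#' @param alignment named gapped strings (or AAStringSet)
#' @param background `"blosum62"` (default) or `"uniform"`
#' @param window flank half-width for optional smoothing (0 = none)
#' @param exclude_ids sequence ids removed before scoring (e.g. a
#'   divergent paralog Group that would only add noise)
#' @param pseudocount residue pseudocount (default 1e-7)
#' @param lambda JSD mixture weight
#' @return numeric vector of scores in `[0, 1]`, one per column, with the
#'   parameters attached as attributes
#' @export
conservation_profile <- function(alignment,
                                 background = c("blosum62", "uniform"),
                                 window = 0L, exclude_ids = NULL,
                                 pseudocount = 1e-7, lambda = 0.5) {
  background <- match.arg(background)
  alignment <- as_alignment(alignment)
  if (!is.null(exclude_ids)) {
    alignment <- alignment[setdiff(names(alignment), exclude_ids)]
    if (length(alignment) == 0L) abort("all sequences excluded")
  }
  len <- nchar(alignment[[1]])
  if (window < 0 || window >= len) {
    abort("window must be in [0, alignment length)",
          "septinevo_invalid_parameter")
  }
  bg <- aa_background(background)
  scores <- vapply(seq_len(len), function(col) {
    cd <- column_distribution(alignment, col, pseudocount)
    if (all(cd$freq == 0)) return(0)
    (1 - cd$gap_fraction) * js_divergence(cd$freq, bg, lambda)
  }, numeric(1))
  if (window > 0) {
    sm <- scores
    for (i in seq_len(len)) {
      fl <- setdiff(max(1, i - window):min(len, i + window), i)
      sm[i] <- 0.5 * scores[i] + 0.5 * mean(scores[fl])
    }
    scores <- sm
  }
  attr(scores, "parameters") <- list(background = background,
                                     window = window,
                                     pseudocount = pseudocount)
  scores
}

#' Map alignment columns to reference residue numbers
#'
#' Columns where the reference sequence is ungapped map to successive
#' residue numbers 1..len(ungapped reference); other columns are
#' unmapped. Used to express column-wise results in the coordinate
#' system of a reference septin (a CDC3-like numbering).
#'
#' @param alignment named gapped strings (or AAStringSet)
#' @param reference_id id of the reference row
#' @return list of class "reference_map": `reference`, `col_to_res`
#'   (named integer vector: column -> residue), `res_to_col` (inverse)
#' @export
map_to_reference <- function(alignment, reference_id) {
  alignment <- as_alignment(alignment)
  if (!reference_id %in% names(alignment)) {
    abort(sprintf("reference '%s' absent from alignment", reference_id))
  }
  chars <- strsplit(alignment[[reference_id]], "")[[1]]
  cols <- which(chars != "-")
  col_to_res <- setNames(seq_along(cols), cols)
  res_to_col <- setNames(cols, seq_along(cols))
  structure(list(reference = reference_id,
                 col_to_res = col_to_res, res_to_col = res_to_col),
            class = "reference_map")
}

# residue number -> alignment column for an arbitrary (gapped) row
row_residue_columns <- function(alignment, id) {
  alignment <- as_alignment(alignment)
  if (!id %in% names(alignment)) {
    abort(sprintf("sequence '%s' absent from alignment", id),
          "septinevo_mapping_error")
  }
  which(strsplit(alignment[[id]], "")[[1]] != "-")
}

#' Count interface positions inside/outside annotated regions
#'
#' Partitions reference positions by membership in named inclusive
#' intervals (conserved motifs and regions such as G1, G3, G4, S1-S4,
#' SUE, the polybasic region). A position inside several regions counts
#' once as inside.
#'
#' @param positions integer reference positions
#' @param region_table data frame with columns `name`, `start`, `end`
#'   (inclusive reference coordinates)
#' @return list (inside, outside, per_region named counts, membership
#'   data frame)
#' @export
motif_overlap <- function(positions, region_table) {
  if (!all(c("name", "start", "end") %in% names(region_table))) {
    abort("region_table needs columns name, start, end")
  }
  if (any(region_table$start > region_table$end)) {
    abort("malformed region interval (start > end)")
  }
  if (length(positions) == 0) {
    return(list(inside = 0L, outside = 0L,
                per_region = setNames(integer(nrow(region_table)),
                                      region_table$name),
                membership = data.frame(position = integer(0),
                                        inside = logical(0))))
  }
  inside_any <- rep(FALSE, length(positions))
  per_region <- setNames(integer(nrow(region_table)), region_table$name)
  for (r in seq_len(nrow(region_table))) {
    hit <- positions >= region_table$start[r] &
      positions <= region_table$end[r]
    per_region[r] <- sum(hit)
    inside_any <- inside_any | hit
  }
  list(inside = sum(inside_any), outside = sum(!inside_any),
       per_region = per_region,
       membership = data.frame(position = positions, inside = inside_any))
}
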