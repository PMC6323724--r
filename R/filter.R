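# Septin candidate identification: G-box motif scanning plus the
# domain/motif retention rule.

#' Default G-box patterns
#'
#' Canonical Ras-superfamily GTPase boxes, expressed as regular
#' expressions: G1 (Walker A) `[AG]x(4)GK[ST]`, G3 `Dx(2)G`, G4 `[NT]KxD`.
#' The boxes are named after the conserved GTPase sequence elements; the
#' patterns are configurable in every function that uses them.
#'
#' @return named character vector of regular expressions
#' @export
gbox_patterns <- function() {
  c(G1 = "[AG].{4}GK[ST]", G3 = "D..G", G4 = "[NT]K.D")
}

# domain label sets of the retention rule
SEPTIN_DOMAINS <- c("P-Loop_NTPase", "CDC3", "CDC_septin")
CONFLICT_DOMAINS <- c("LysM", "DNA_binding")

split_domains <- function(x) {
  if (is.na(x) || x == "") return(character(0))
  trimws(strsplit(x, ",")[[1]])
}

#' Scan a protein sequence for G boxes
#'
#' Finds at most one hit per box (G1, G3, G4). Because the short G3
#' pattern is common, hits must form a chain consistent with a single
#' GTPase domain: starts ordered G1 < G3 < G4, and the full chain spanning
#' at most `max_span` residues. Among consistent chains the one with the
#' most boxes is kept, ties broken towards the leftmost positions.
#'
#' @param sequence amino-acid string (letters from the 20 standard amino
#'   acids plus X)
#' @param patterns named regex vector, see [gbox_patterns()]
#' @param max_span maximum span in residues from first to last box
#' @return data frame (motif_id, start, matched), ordered by start;
#'   zero rows when no box is found
#' @export
scan_gboxes <- function(sequence, patterns = gbox_patterns(),
                        max_span = 400L) {
  if (!is.character(sequence) || length(sequence) != 1L ||
      is.na(sequence) || nchar(sequence) == 0L) {
    abort("`sequence` must be a non-empty string")
  }
  if (grepl(sprintf("[^%sX-]", paste(AA20, collapse = "")), sequence)) {
    abort("`sequence` contains letters outside the amino-acid alphabet")
  }
  # all matches per box (capped defensively)
  hits <- lapply(patterns, function(p) {
    m <- gregexpr(p, sequence)[[1]]
    if (m[1] == -1) return(data.frame(start = integer(0), len = integer(0)))
    data.frame(start = as.integer(m),
               len = attr(m, "match.length"))[seq_len(min(length(m), 25L)), ,
                                              drop = FALSE]
  })
  ids <- names(patterns)
  # enumerate choices: for each box either absent (0) or one of its hits
  choices <- lapply(hits, function(h) 0:nrow(h))
  grid <- expand.grid(choices, KEEP.OUT.ATTRS = FALSE)
  best <- NULL
  best_key <- NULL
  for (r in seq_len(nrow(grid))) {
    sel <- as.integer(grid[r, ])
    present <- which(sel > 0)
    if (length(present) == 0) next
    starts <- mapply(function(i, j) hits[[i]]$start[j], present, sel[present])
    ends <- starts + mapply(function(i, j) hits[[i]]$len[j],
                            present, sel[present]) - 1L
    if (is.unsorted(starts, strictly = TRUE)) next   # enforce G1 < G3 < G4
    if (max(ends) - min(starts) + 1L > max_span) next
    key <- c(-length(present), starts,
             rep(Inf, length(ids) - length(present)))
    if (is.null(best_key) ||
        isTRUE(order_lex(key, best_key) < 0)) {
      best_key <- key
      best <- data.frame(
        motif_id = ids[present], start = as.integer(starts),
        matched = substring(sequence, starts, ends),
        stringsAsFactors = FALSE)
    }
  }
  if (is.null(best)) {
    return(data.frame(motif_id = character(0), start = integer(0),
                      matched = character(0), stringsAsFactors = FALSE))
  }
  best[order(best$start), , drop = FALSE]
}

# lexicographic comparison of equal-length numeric keys: -1, 0 or 1
order_lex <- function(a, b) {
  for (i in seq_along(a)) {
    if (a[i] < b[i]) return(-1L)
    if (a[i] > b[i]) return(1L)
  }
  0L
}

#' Classify one candidate under the retention rule
#'
#' A protein is retained if it carries a recognised septin domain
#' (P-Loop_NTPase, CDC3 or CDC_septin; `domain_pass`), or else if it has
#' at least two distinct G boxes and no conflicting domain (LysM or
#' DNA_binding; `gbox_pass`). The domain route takes precedence, so a
#' known septin like S. cerevisiae CDC3 is retained even when fewer than
#' three boxes are recognised in its sequence. Otherwise the protein is
#' rejected with reason `conflict_fail` (two boxes but a conflicting
#' domain) or `insufficient_fail`.
#'
#' @param record one proteome record (list or one-row data frame with
#'   `id`, `sequence`, `domain_labels`)
#' @param hits G-box hits from [scan_gboxes()] on `record$sequence`
#'   (computed if omitted)
#' @param septin_domains,conflict_domains domain label sets
#' @return list (id, retained, reason)
#' @export
classify_candidate <- function(record, hits = NULL,
                               septin_domains = SEPTIN_DOMAINS,
                               conflict_domains = CONFLICT_DOMAINS) {
  if (is.null(hits)) hits <- scan_gboxes(record$sequence)
  doms <- split_domains(record$domain_labels)
  n_boxes <- length(unique(hits$motif_id))
  if (length(intersect(doms, septin_domains)) > 0) {
    return(list(id = record$id, retained = TRUE, reason = "domain_pass"))
  }
  if (n_boxes >= 2) {
    if (length(intersect(doms, conflict_domains)) > 0) {
      return(list(id = record$id, retained = FALSE,
                  reason = "conflict_fail"))
    }
    return(list(id = record$id, retained = TRUE, reason = "gbox_pass"))
  }
  list(id = record$id, retained = FALSE, reason = "insufficient_fail")
}

#' Filter a proteome with the septin retention rule
#'
#' Applies [classify_candidate()] to every record. Decisions depend only
#' on the record itself, so the output order follows the input order and
#' permuting the input permutes the output identically.
#'
#' @param records proteome records data frame (id, taxon, sequence,
#'   domain_labels); ids must be unique
#' @param patterns,max_span passed to [scan_gboxes()]
#' @param septin_domains,conflict_domains passed to [classify_candidate()]
#' @return list with `retained` (subset of `records`, input order) and
#'   `decisions` (data frame: id, retained, reason)
#' @export
filter_proteome <- function(records, patterns = gbox_patterns(),
                            max_span = 400L,
                            septin_domains = SEPTIN_DOMAINS,
                            conflict_domains = CONFLICT_DOMAINS) {
  if (anyDuplicated(records$id)) {
    abort("duplicate protein ids in proteome")
  }
  if (nrow(records) == 0L) {
    return(list(retained = records,
                decisions = data.frame(id = character(0),
                                       retained = logical(0),
                                       reason = character(0))))
  }
  decisions <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    hits <- scan_gboxes(rec$sequence, patterns, max_span)
    as.data.frame(classify_candidate(rec, hits, septin_domains,
                                     conflict_domains),
                  stringsAsFactors = FALSE)
  }))
  list(retained = records[decisions$retained, , drop = FALSE],
       decisions = decisions)
}
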