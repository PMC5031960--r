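# Homolog screening by exact affine-gap local alignment.
#
# The screen that matters at desk scale is the identity/coverage filter:
# exact Smith-Waterman alignment (via Biostrings) replaces a seeded
# database heuristic, with the >= 35% identity and >= 50% query-coverage
# thresholds as the operative filters.

get_submat <- function(name) {
  e <- new.env()
  ok <- tryCatch({
    utils::data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e)) {
    stop_input("unknown substitution matrix '", name, "'")
  }
  m <- get(name, envir = e)
  # tolerate X: scored 0 against everything
  if ("X" %in% rownames(m)) {
    m["X", ] <- 0L
    m[, "X"] <- 0L
  }
  m
}

#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman alignment under affine gap costs (a gap of
#' length L costs `gap_open + L * gap_extend`). Percent identity is
#' identical columns over aligned columns (gaps included in the
#' denominator); query coverage is the aligned span of the query over
#' its full length. Ties between equal-scoring alignments are broken
#' deterministically by the dynamic-programming traceback order.
#'
#' @param a query protein sequence (standard alphabet; `X` tolerated,
#'   scored 0).
#' @param b subject protein sequence.
#' @param matrix substitution matrix name (default `"BLOSUM62"`).
#' @param gap_open,gap_extend gap cost parameters (protein-BLAST-style
#'   defaults 11/1; `gap_open = 0, gap_extend = k` gives a linear
#'   penalty of k per gap column).
#' @param query_id,subject_id identifiers carried into the result.
#' @return A one-row tibble: `query_id`, `subject_id`,
#'   `percent_identity`, `query_coverage`, `score`, `aligned_query`,
#'   `aligned_subject`, `trimmed_subject`, and aligned span coordinates.
#' @examples
#' local_align("HEAGAWGHEE", "PAWHEAE", matrix = "BLOSUM50",
#'             gap_open = 0, gap_extend = 8)
#' @export
local_align <- function(a, b, matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                        query_id = "query", subject_id = "subject") {
  if (!nzchar(a) || !nzchar(b)) stop_input("sequences must be nonempty")
  m <- get_submat(matrix)
  al <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b), type = "local",
    substitutionMatrix = m, gapOpening = gap_open, gapExtension = gap_extend
  )
  pat <- Biostrings::pattern(al)
  sub <- Biostrings::subject(al)
  s_start <- Biostrings::start(sub); s_end <- Biostrings::end(sub)
  aligned_q <- as.character(Biostrings::alignedPattern(al))
  aligned_s <- as.character(Biostrings::alignedSubject(al))
  ident <- sum(strsplit(aligned_q, "")[[1]] == strsplit(aligned_s, "")[[1]])
  ncol_al <- nchar(aligned_q)
  tibble::tibble(
    query_id = query_id, subject_id = subject_id,
    percent_identity = if (ncol_al > 0) 100 * ident / ncol_al else 0,
    query_coverage = (Biostrings::end(pat) - Biostrings::start(pat) + 1) / nchar(a),
    score = Biostrings::score(al),
    aligned_query = aligned_q, aligned_subject = aligned_s,
    trimmed_subject = substr(b, s_start, s_end),
    q_start = Biostrings::start(pat), q_end = Biostrings::end(pat),
    s_start = s_start, s_end = s_end
  )
}

#' Screen a sequence database for homologs of a query
#'
#' Aligns the query against every database sequence and keeps hits with
#' `percent_identity >= min_identity` and
#' `query_coverage >= min_coverage`. Subject sequence extending beyond
#' the aligned span is trimmed (`trimmed_subject`). Hits are sorted by
#' descending score, ties by subject id.
#'
#' @param query protein sequence (the reference homolog).
#' @param db named character vector or `AAStringSet` of subject
#'   sequences.
#' @param min_identity minimum percent identity (default 35).
#' @param min_coverage minimum query coverage fraction (default 0.5).
#' @param keep_all return discarded hits too (with `kept`/`reason`
#'   columns)?
#' @inheritParams local_align
#' @return A tibble of hits (one row per subject passing both filters,
#'   or all subjects annotated when `keep_all = TRUE`).
#' @export
screen_homologs <- function(query, db, min_identity = 35, min_coverage = 0.5,
                            matrix = "BLOSUM62", gap_open = 11, gap_extend = 1,
                            query_id = "query", keep_all = FALSE) {
  if (min_identity < 0 || min_identity > 101) stop_input("min_identity must be a percentage")
  if (min_coverage < 0 || min_coverage > 1) stop_input("min_coverage must be in [0,1]")
  if (inherits(db, "AAStringSet")) db <- setNames(as.character(db), names(db))
  if (length(db) == 0) {
    return(tibble::tibble(query_id = character(), subject_id = character(),
                          percent_identity = numeric(), query_coverage = numeric(),
                          score = numeric(), aligned_query = character(),
                          aligned_subject = character(), trimmed_subject = character(),
                          q_start = integer(), q_end = integer(),
                          s_start = integer(), s_end = integer(),
                          kept = logical(), reason = character()))
  }
  if (is.null(names(db))) names(db) <- paste0("seq", seq_along(db))
  hits <- dplyr::bind_rows(lapply(names(db), function(id) {
    local_align(query, db[[id]], matrix = matrix, gap_open = gap_open,
                gap_extend = gap_extend, query_id = query_id, subject_id = id)
  }))
  hits$kept <- hits$percent_identity >= min_identity &
    hits$query_coverage >= min_coverage
  hits$reason <- dplyr::case_when(
    hits$kept ~ "pass",
    hits$percent_identity < min_identity & hits$query_coverage < min_coverage ~
      "identity+coverage",
    hits$percent_identity < min_identity ~ "identity",
    TRUE ~ "coverage"
  )
  hits <- dplyr::arrange(hits, dplyr::desc(.data$score), .data$subject_id)
  if (keep_all) hits else dplyr::select(
    dplyr::filter(hits, .data$kept), -"kept", -"reason"
  )
}

#' Keep one isoform per genetic locus
#'
#' Collapses alignment hits so that at most one isoform survives per
#' locus: the highest-scoring one, ties broken by longer trimmed
#' sequence then lexicographic subject id. Subjects missing from the
#' locus map are kept as their own singleton loci with a warning.
#'
#' @param hits a tibble from [screen_homologs()].
#' @param locus_map a data frame with columns `gene_id` and `locus_id`.
#' @return The deduplicated hits tibble.
#' @export
dedup_isoforms <- function(hits, locus_map) {
  if (nrow(hits) == 0) return(hits)
  loc <- setNames(locus_map$locus_id, locus_map$gene_id)
  missing <- setdiff(hits$subject_id, names(loc))
  if (length(missing)) {
    warn(paste0("subjects missing from locus map treated as singleton loci: ",
                paste(missing, collapse = ", ")))
  }
  hits$.locus <- ifelse(hits$subject_id %in% names(loc),
                        loc[hits$subject_id],
                        paste0("singleton:", hits$subject_id))
  out <- hits |>
    dplyr::group_by(.data$.locus) |>
    dplyr::arrange(dplyr::desc(.data$score),
                   dplyr::desc(nchar(.data$trimmed_subject)),
                   .data$subject_id, .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup() |>
    dplyr::select(-".locus") |>
    dplyr::arrange(dplyr::desc(.data$score), .data$subject_id)
  out
}
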