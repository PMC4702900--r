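#' Best-hit ortholog call per query and target species
#'
#' For each (query, target species) pair, keeps the hit with the lowest
#' E-value as the most conserved counterpart. Ties on E-value are broken by
#' higher bit score, then lexicographically smaller subject id, for
#' determinism. Hits are assumed to be pre-filtered at the search E-value
#' cutoff (the sequence search is run externally, e.g. BLASTN with
#' `-task blastn -word_size 6 -evalue 1e-5 -strand plus`, and ingested with
#' [read_blast_tab()]).
#'
#' @param hits Data frame with columns `query_id`, `subject_id`,
#'   `target_species`, `e_value`, `bit_score`.
#' @return Data frame with one row per (query, species): `query_id`,
#'   `target_species`, `best_subject_id`, `best_e_value`, `best_bit_score`.
#'   Queries with no hits in a species are absent for that species.
#' @export
best_hit_per_query <- function(hits) {
  req <- c("query_id", "subject_id", "target_species", "e_value", "bit_score")
  if (!all(req %in% names(hits))) {
    stop("hits must have columns: ", paste(req, collapse = ", "))
  }
  if (nrow(hits) == 0L) {
    return(data.frame(query_id = character(), target_species = character(),
                      best_subject_id = character(), best_e_value = numeric(),
                      best_bit_score = numeric(), stringsAsFactors = FALSE))
  }
  stopifnot(all(hits$e_value >= 0))
  ord <- order(hits$query_id, hits$target_species, hits$e_value,
               -hits$bit_score, hits$subject_id)
  hits <- hits[ord, ]
  first <- !duplicated(hits[, c("query_id", "target_species")])
  best <- hits[first, ]
  data.frame(
    query_id = best$query_id,
    target_species = best$target_species,
    best_subject_id = best$subject_id,
    best_e_value = best$e_value,
    best_bit_score = best$bit_score,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Label the conservation lineage of a query
#'
#' Given the set of species in which a query has at least one best-hit
#' ortholog, returns the most specific configured clade containing all of
#' them plus the query's own species. An empty presence set yields
#' `"species-specific"`. A proper clade (one not spanning every configured
#' species) is labelled `"<clade>-specific"`; the clade spanning all species
#' is labelled `"<clade>-conserved"`.
#'
#' @param query_species Species code of the query.
#' @param presence_species Character vector of species with an ortholog
#'   (may be empty).
#' @param clades Named list of character vectors; each entry is a clade and
#'   its member species. Clades must jointly cover every species used.
#' @return Character scalar label.
#' @export
lineage_label <- function(query_species, presence_species, clades) {
  stopifnot(is.list(clades), length(clades) >= 1L, !is.null(names(clades)))
  all_species <- unique(unlist(clades))
  needed <- union(query_species, presence_species)
  missing_sp <- setdiff(needed, all_species)
  if (length(missing_sp)) {
    stop("species not present in any clade: ",
         paste(missing_sp, collapse = ", "))
  }
  if (length(presence_species) == 0L) return("species-specific")
  covering <- Filter(function(members) all(needed %in% members), clades)
  if (length(covering) == 0L) {
    stop("no configured clade covers species: ",
         paste(needed, collapse = ", "))
  }
  sizes <- vapply(covering, length, integer(1))
  clade_name <- names(covering)[which.min(sizes)]
  if (setequal(clades[[clade_name]], all_species)) {
    paste0(clade_name, "-conserved")
  } else {
    paste0(clade_name, "-specific")
  }
}

#' Read clade definitions from a key-value config file
#'
#' Flat text format, one clade per line: `cladeName = sp1,sp2,sp3`.
#' Blank lines and `#` comments are ignored.
#'
#' @param path Path to the config file.
#' @return Named list of species-code vectors suitable for [lineage_label()].
#' @export
read_clades <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !grepl("^\\s*#", lines)]
  out <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L) stop("malformed clade line: ", ln)
    out[[trimws(kv[1L])]] <- trimws(strsplit(kv[2L], ",")[[1L]])
  }
  out
}
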