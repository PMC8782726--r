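# Compound set I/O and standardisation.
#
# A compound set is an ordinary data.frame with one row per input entry:
#   id               unique identifier (auto-generated ordinal if absent)
#   raw_smiles       the SMILES string as read
#   canonical_smiles canonical form, NA unless status == "ok"
#   n_heavy_atoms    heavy-atom count, NA unless status == "ok"
#   status           "ok", "parse_failed", or "filtered"
#   reason           rejection reason for filtered records, NA otherwise

.mol_set <- function(id, raw_smiles) {
  can <- ob_canonical(raw_smiles)
  data.frame(
    id = id,
    raw_smiles = raw_smiles,
    canonical_smiles = can,
    n_heavy_atoms = smiles_heavy_atoms(can),
    status = ifelse(is.na(can), "parse_failed", "ok"),
    reason = NA_character_,
    stringsAsFactors = FALSE
  )
}

.fatal_input <- function(msg) {
  stop(errorCondition(msg, class = c("triscreen_input_error", "error")))
}

.fatal_config <- function(msg) {
  stop(errorCondition(msg, class = c("triscreen_config_error", "error")))
}

.fatal_empty <- function(msg) {
  stop(errorCondition(msg, class = c("triscreen_empty_error", "error")))
}

#' Read a compound library
#'
#' Reads `.smi` (whitespace-separated SMILES + optional ID, `#` comments
#' ignored), CSV (columns `id`, `smiles`) or SDF (molecule title as ID) into
#' a compound set. Input order is preserved; unparsable entries are kept with
#' `status = "parse_failed"` rather than aborting the run. IDs missing from
#' the input are auto-generated as zero-padded ordinals.
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"smi"`, `"csv"` or `"sdf"`.
#' @return compound set data.frame (see package overview).
#' @export
read_library <- function(path, format = c("auto", "smi", "csv", "sdf")) {
  format <- match.arg(format)
  if (!file.exists(path)) .fatal_input(paste0("input file not found: ", path))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, smi = "smi", csv = "csv", sdf = "sdf",
                     .fatal_input(paste0("cannot infer format from extension: ", path)))
  }

  if (format == "smi") {
    lines <- readLines(path, warn = FALSE)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    if (length(lines) == 0L) .fatal_input(paste0("empty library file: ", path))
    parts <- strsplit(lines, "[ \t]+")
    smi <- vapply(parts, `[[`, "", 1L)
    ids <- vapply(parts, function(p) if (length(p) > 1L) p[2L] else NA_character_, "")
  } else if (format == "csv") {
    tab <- utils::read.csv(path, stringsAsFactors = FALSE)
    if (!all(c("id", "smiles") %in% names(tab)))
      .fatal_input("CSV library must have columns 'id' and 'smiles'")
    if (nrow(tab) == 0L) .fatal_input(paste0("empty library file: ", path))
    smi <- as.character(tab$smiles)
    ids <- as.character(tab$id)
  } else {
    sdf <- tryCatch(ChemmineR::read.SDFset(path),
                    error = function(e) .fatal_input(paste0("cannot read SDF: ", path)))
    if (length(sdf) == 0L) .fatal_input(paste0("empty library file: ", path))
    smi <- as.character(ChemmineR::sdf2smiles(sdf))
    ids <- vapply(seq_along(sdf), function(i) {
      h <- ChemmineR::header(sdf[[i]])
      nm <- unname(h["Molecule_Name"])
      if (is.na(nm) || !nzchar(trimws(nm))) NA_character_ else trimws(nm)
    }, "")
  }

  auto <- sprintf("CMP%0*d", max(4L, nchar(length(smi))), seq_along(smi))
  ids[is.na(ids) | !nzchar(ids)] <- auto[is.na(ids) | !nzchar(ids)]
  if (anyDuplicated(ids))
    .fatal_input(paste0("duplicate compound IDs: ",
                        paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  .mol_set(ids, smi)
}

#' Standardisation policy
#'
#' @param keep_largest_fragment strip salts/solvates, keeping the fragment
#'   with the most heavy atoms (ties broken by lexicographically smaller
#'   canonical SMILES, and logged).
#' @param neutralize neutralise formal charges where chemically possible.
#' @return a `standardization_policy` list.
#' @export
standardization_policy <- function(keep_largest_fragment = TRUE,
                                   neutralize = TRUE) {
  structure(list(keep_largest_fragment = keep_largest_fragment,
                 neutralize = neutralize),
            class = "standardization_policy")
}

#' Standardise a compound set
#'
#' Applies the standardisation policy to every parsable record: charge
#' neutralisation (engine `neutralize` operation), largest-organic-fragment
#' selection, and re-canonicalisation. Idempotent: standardising an already
#' standardised set is a no-op. Unparsable records pass through unchanged.
#'
#' @param records compound set from [read_library()].
#' @param policy a [standardization_policy()].
#' @return the compound set with updated `canonical_smiles`/`n_heavy_atoms`.
#' @export
standardize <- function(records, policy = standardization_policy()) {
  ok <- which(records$status == "ok")
  if (length(ok) == 0L) return(records)
  smi <- records$canonical_smiles[ok]

  if (isTRUE(policy$neutralize)) {
    neut <- .ob_neutralize(smi)
    smi <- ifelse(is.na(neut), smi, neut)
  }
  if (isTRUE(policy$keep_largest_fragment)) {
    smi <- vapply(smi, .largest_fragment, "", USE.NAMES = FALSE)
  }
  # re-canonicalise so the output is in the engine's canonical dialect
  can <- ob_canonical(smi)
  keep <- !is.na(can)
  records$canonical_smiles[ok[keep]] <- can[keep]
  records$n_heavy_atoms[ok] <- smiles_heavy_atoms(records$canonical_smiles[ok])
  records
}

.ob_neutralize <- function(smiles) {
  n <- length(smiles)
  out <- rep(NA_character_, n)
  has_charge <- grepl("[+-]", smiles)
  out[!has_charge] <- smiles[!has_charge]
  idx <- which(has_charge)
  if (length(idx)) {
    inp <- paste0(smiles[idx], " T", seq_along(idx), collapse = "\n")
    res <- ob_quiet(ChemmineOB::convertFormat(
      "SMI", "CAN", inp, options = data.frame(names = "neutralize", args = "")))
    lines <- strsplit(res, "\n", fixed = TRUE)[[1]]
    lines <- lines[nzchar(trimws(lines))]
    if (length(lines)) {
      parts <- strsplit(lines, "[ \t]+")
      got <- as.integer(sub("^T", "", vapply(parts, function(p) p[length(p)], "")))
      out[idx[got]] <- vapply(parts, `[[`, "", 1L)
    }
  }
  out
}

.largest_fragment <- function(smiles) {
  frags <- strsplit(smiles, ".", fixed = TRUE)[[1]]
  if (length(frags) == 1L) return(smiles)
  can <- ob_canonical(frags)
  frags <- frags[!is.na(can)]
  can <- can[!is.na(can)]
  if (length(can) == 0L) return(smiles)
  nha <- smiles_heavy_atoms(can)
  best <- which(nha == max(nha))
  if (length(best) > 1L) {
    pick <- best[order(can[best])][1L]
    message("fragment tie in '", smiles, "': keeping '", can[pick], "'")
    best <- pick
  }
  can[best]
}

#' Corpus filter rules
#'
#' Default pre-training corpus curation: organic-element whitelist, heavy-atom
#' size window, parsable, single fragment. Every rule is exposed so the
#' curation can be tightened or relaxed per corpus.
#'
#' @param elements allowed chemical elements.
#' @param min_heavy,max_heavy inclusive heavy-atom bounds.
#' @param single_fragment require a connected (single-fragment) molecule.
#' @param dedup drop repeated canonical SMILES (first occurrence kept).
#' @return a `corpus_filter_rules` list.
#' @export
corpus_filter_rules <- function(elements = c("H", "B", "C", "N", "O", "F",
                                             "P", "S", "Cl", "Br", "I"),
                                min_heavy = 3L, max_heavy = 100L,
                                single_fragment = TRUE, dedup = TRUE) {
  structure(list(elements = elements, min_heavy = min_heavy,
                 max_heavy = max_heavy, single_fragment = single_fragment,
                 dedup = dedup),
            class = "corpus_filter_rules")
}

#' Filter a pre-training corpus
#'
#' Retains standardised records passing all corpus rules; the rest are
#' dropped, each with a reason. Order is preserved. Per-rule rejection
#' counts are attached as attribute `"rejections"`.
#'
#' @param records standardised compound set.
#' @param rules a [corpus_filter_rules()].
#' @return the retained subset, with a `rejections` attribute
#'   (data.frame `id`, `reason`).
#' @export
filter_pretraining_corpus <- function(records, rules = corpus_filter_rules()) {
  reason <- rep(NA_character_, nrow(records))
  reason[records$status != "ok"] <- "parse"

  idx <- which(is.na(reason))
  if (length(idx)) {
    for (i in idx) {
      els <- smiles_elements(records$canonical_smiles[i])
      if (!all(els %in% rules$elements)) reason[i] <- "element"
    }
    idx <- idx[is.na(reason[idx])]
    nha <- records$n_heavy_atoms[idx]
    bad_size <- nha < rules$min_heavy | nha > rules$max_heavy
    reason[idx[bad_size]] <- "size"

    if (rules$single_fragment) {
      idx2 <- idx[!bad_size]
      multi <- grepl(".", records$canonical_smiles[idx2], fixed = TRUE)
      reason[idx2[multi]] <- "fragment"
    }
  }
  if (isTRUE(rules$dedup)) {
    left <- which(is.na(reason))
    dup <- left[duplicated(records$canonical_smiles[left])]
    reason[dup] <- "duplicate"
  }

  keep <- records[is.na(reason), , drop = FALSE]
  rej <- data.frame(id = records$id[!is.na(reason)],
                    reason = reason[!is.na(reason)],
                    stringsAsFactors = FALSE)
  if (nrow(keep) == 0L) {
    counts <- table(rej$reason)
    .fatal_empty(paste0(
      "corpus empty after filtering (",
      paste(sprintf("%s: %d", names(counts), as.integer(counts)), collapse = ", "),
      ")"))
  }
  rownames(keep) <- NULL
  attr(keep, "rejections") <- rej
  keep
}

#' Write a screening results table
#'
#' TSV, one row per screened compound, sorted by aggregate score descending
#' (ties broken by compound ID ascending), floats at 6 decimal places.
#'
#' @param ranking a `candidate_ranking` from [rank_candidates()].
#' @param path output path.
#' @export
write_results_table <- function(ranking, path) {
  tab <- if (inherits(ranking, "candidate_ranking")) ranking$rows else ranking
  num <- c("s1d_raw", "s2d_raw", "s3d_raw", "s_aggregate", "filtered_score")
  out <- tab
  for (cn in num) out[[cn]] <- ifelse(is.na(tab[[cn]]), "NA",
                                      sprintf("%.6f", tab[[cn]]))
  ok <- tryCatch({
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = TRUE)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) .fatal_input(paste0("cannot write results table: ", path))
  invisible(path)
}

#' Read back a results table written by [write_results_table()]
#' @param path TSV path.
#' @return data.frame with the ranking columns.
#' @export
read_results_table <- function(path) {
  if (!file.exists(path)) .fatal_input(paste0("results table not found: ", path))
  utils::read.delim(path, stringsAsFactors = FALSE)
}

#' Write a compound set as a .smi file
#' @param records compound set.
#' @param path output path.
#' @param canonical write canonical (default) or raw SMILES.
#' @export
write_smi <- function(records, path, canonical = TRUE) {
  smi <- if (canonical) records$canonical_smiles else records$raw_smiles
  keep <- !is.na(smi)
  writeLines(paste(smi[keep], records$id[keep]), path)
  invisible(path)
}
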