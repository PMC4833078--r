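#' Read a protein FASTA file into a protein tibble
#'
#' Parses a protein FASTA file into the package's standard protein table.
#' Sequences are uppercased, stop characters (`*`) are stripped from the
#' sequence ends, and any letter outside the 21-letter alphabet (20 canonical
#' amino acids plus `X`) is rejected. Internal `*` characters indicate a
#' truncated gene model and raise an error naming the offending record.
#'
#' The record identifier is the first whitespace-delimited token of the
#' header. A `family=<name>` token elsewhere in the header is parsed into a
#' `family` column (used for query sets); records without one get `NA`.
#'
#' @param path Path to a protein FASTA file.
#' @param species Species label attached to every record.
#' @return A tibble with columns `species`, `protein_id`, `sequence` and
#'   `family`, in file order.
#' @export
read_fasta <- function(path, species = "unknown") {
  if (!file.exists(path)) abort(paste0("no such file: ", path))
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) {
    # an empty proteome is legitimate (e.g. a species with no predictions)
    return(tibble(species = character(0), protein_id = character(0),
                  sequence = character(0), family = character(0)))
  }
  if (!startsWith(lines[[1]], ">")) {
    abort(paste0("malformed FASTA (no leading '>'): ", path))
  }
  hdr_idx <- which(startsWith(lines, ">"))
  starts <- hdr_idx + 1L
  ends <- c(hdr_idx[-1] - 1L, length(lines))
  headers <- sub("^>", "", lines[hdr_idx])
  ids <- vapply(strsplit(trimws(headers), "\\s+"),
                function(x) x[[1]], character(1))
  fams <- stringr::str_match(headers, "family=(\\S+)")[, 2]
  seqs <- vapply(seq_along(hdr_idx), function(i) {
    if (starts[i] > ends[i]) return("")
    paste(lines[starts[i]:ends[i]], collapse = "")
  }, character(1))
  seqs <- toupper(gsub("[[:space:]]", "", seqs))
  seqs <- gsub("^\\*+|\\*+$", "", seqs)
  for (i in seq_along(ids)) {
    if (!nzchar(ids[i]) || grepl("\\s", ids[i])) {
      abort(paste0("malformed FASTA header at record ", i, " of ", path))
    }
    if (!nzchar(seqs[i])) {
      abort(paste0("empty sequence for record '", ids[i], "' in ", path))
    }
    if (grepl("\\*", seqs[i], fixed = FALSE)) {
      abort(paste0("internal stop codon '*' in record '", ids[i], "'"))
    }
    if (!valid_aa(seqs[i])) {
      bad <- setdiff(unique(strsplit(seqs[i], "")[[1]]), AA_ALPHABET)
      abort(paste0("record '", ids[i], "' contains letters outside the ",
                   "21-letter alphabet: ", paste(bad, collapse = ", ")))
    }
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    abort(paste0("duplicate protein ids in ", path, ": ",
                 paste(dup, collapse = ", ")))
  }
  tibble(species = species, protein_id = ids, sequence = seqs,
         family = fams)
}

#' Write a protein tibble to FASTA
#'
#' Inverse of [read_fasta()]. If a non-`NA` `family` column is present it is
#' emitted as a `family=<name>` header token so query sets round-trip.
#'
#' @param proteins Tibble with `protein_id`, `sequence` and optionally
#'   `family`.
#' @param path Output path.
#' @param width Line-wrap width for sequence lines.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  fam <- if ("family" %in% names(proteins)) proteins$family else
    rep(NA_character_, nrow(proteins))
  out <- character(0)
  for (i in seq_len(nrow(proteins))) {
    hdr <- paste0(">", proteins$protein_id[i],
                  if (!is.na(fam[i])) paste0(" family=", fam[i]) else "")
    body <- gsub(paste0("(.{1,", width, "})"), "\\1\n",
                 proteins$sequence[i])
    out <- c(out, hdr, strsplit(body, "\n")[[1]])
  }
  writeLines(out, path)
  invisible(path)
}

# Canonical annotation-table column order (documented file format).
ANNOTATION_COLS <- c("species", "protein_id", "family", "rbh", "cluster",
                     "profile", "architecture", "functional")

# Serialise a named list/character of functional key=value calls to a
# canonical (key-sorted) semicolon string.
pack_functional <- function(x) {
  vapply(x, function(kv) {
    if (is.null(kv) || length(kv) == 0) return(".")
    kv <- unlist(kv)
    kv <- kv[order(names(kv))]
    paste(paste0(names(kv), "=", kv), collapse = ";")
  }, character(1))
}

unpack_functional <- function(s) {
  lapply(s, function(x) {
    if (is.na(x) || x == ".") return(character(0))
    parts <- strsplit(x, ";", fixed = TRUE)[[1]]
    kv <- strsplit(parts, "=", fixed = TRUE)
    stats::setNames(vapply(kv, `[`, character(1), 2),
                    vapply(kv, `[`, character(1), 1))
  })
}

#' Write an annotation table to TSV
#'
#' Writes accepted family assignments as a tab-separated table with a fixed
#' header (`species protein_id family rbh cluster profile architecture
#' functional`). Rows are sorted lexicographically by (species, family,
#' protein_id) so output is byte-deterministic regardless of insertion
#' order. The `functional` column holds key-sorted `key=value` pairs joined
#' by `;` (`.` when empty).
#'
#' @param records Annotation tibble as produced by [integrate_evidence()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_annotation_table <- function(records, path) {
  df <- tibble(
    species = as.character(records$species),
    protein_id = as.character(records$protein_id),
    family = as.character(records$family),
    rbh = as.logical(records$rbh),
    cluster = as.logical(records$cluster),
    profile = as.logical(records$profile),
    architecture = as.logical(records$architecture),
    functional = if (is.list(records$functional))
      pack_functional(records$functional) else as.character(records$functional)
  )
  ok <- df$rbh | df$cluster | df$profile | df$architecture
  if (nrow(df) && !all(ok)) {
    abort(paste0("annotation records without any evidence flag: ",
                 paste(df$protein_id[!ok], collapse = ", ")))
  }
  df <- df[order(df$species, df$family, df$protein_id), ]
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read an annotation table written by [write_annotation_table()]
#'
#' @param path Path to the TSV.
#' @return Annotation tibble; `functional` is a list-column of named
#'   character vectors.
#' @export
read_annotation_table <- function(path) {
  df <- readr::read_tsv(path, col_types = readr::cols(
    species = "c", protein_id = "c", family = "c", rbh = "l",
    cluster = "l", profile = "l", architecture = "l", functional = "c"))
  df$functional <- unpack_functional(df$functional)
  tibble::as_tibble(df)
}

#' Read a family-rule configuration
#'
#' The configuration is a YAML document with three top-level blocks:
#'
#' ```yaml
#' motifs:
#'   GCGEQ: GCGEQ
#'   NIM:   CXPXCXXXCXNGXCXXPXXCXCXXGY
#' anchors:
#'   pgrp_triad:
#'     reference_id: PGRP_REF
#'     positions: [71, 88, 96]
#'     expected: [C, H, H]
#' families:
#'   PGRP:
#'     required_domains: {PGRP: 1}
#'     forbidden_domains: []
#'     required_motifs: []
#'     residue_anchors: [pgrp_triad]
#'     localization: any
#' ```
#'
#' `required_domains` maps domain names to minimum counts; the pseudo-domain
#' names `TM`, `LRR` and `SIGNAL` refer to predicted structural features
#' rather than PSSM hits. `expected` entries may be multi-letter strings
#' (any of the listed residues is accepted at that anchor position).
#'
#' @param path Path to the YAML configuration.
#' @return An object of class `family_rules`: a list with `rules` (tibble,
#'   one row per family with list-columns), `anchors` (tibble) and `motifs`
#'   (named character vector of degenerate patterns).
#' @export
read_family_rules <- function(path) {
  raw <- yaml::yaml.load(paste(readLines(path), collapse = "\n"))
  fams <- raw$families
  if (is.null(fams) || length(fams) == 0) abort("config declares no families")
  if (anyDuplicated(names(fams))) {
    abort(paste0("family declared twice: ",
                 paste(unique(names(fams)[duplicated(names(fams))]),
                       collapse = ", ")))
  }
  rules <- purrr::map2_dfr(names(fams), fams, function(fam, r) {
    req <- r$required_domains
    req_tbl <- if (length(req))
      tibble(domain = names(req), min_count = as.integer(unlist(req)))
    else tibble(domain = character(0), min_count = integer(0))
    forb <- as.character(unlist(r$forbidden_domains))
    if (length(intersect(req_tbl$domain, forb))) {
      abort(paste0("family ", fam, ": required and forbidden domains overlap"))
    }
    motifs <- as.character(unlist(r$required_motifs))
    if (nrow(req_tbl) == 0 && length(motifs) == 0) {
      abort(paste0("family ", fam,
                   ": needs at least one required domain or motif"))
    }
    loc <- r$localization %||% "any"
    if (!loc %in% c("secreted", "transmembrane", "intracellular", "any")) {
      abort(paste0("family ", fam, ": unknown localization '", loc, "'"))
    }
    cls <- r$classifier %||% "none"
    if (!cls %in% c("anchored", "tep", "tlr", "relish", "none")) {
      abort(paste0("family ", fam, ": unknown classifier '", cls, "'"))
    }
    tibble(family = fam, required_domains = list(req_tbl),
           forbidden_domains = list(forb), required_motifs = list(motifs),
           residue_anchors = list(as.character(unlist(r$residue_anchors))),
           localization = loc, classifier = cls,
           report_motifs = list(as.character(unlist(r$report_motifs))))
  })
  anchors <- purrr::map2_dfr(names(raw$anchors %||% list()),
                             raw$anchors %||% list(), function(id, a) {
    pos <- as.integer(unlist(a$positions))
    if (is.unsorted(pos, strictly = TRUE)) {
      abort(paste0("anchor ", id, ": positions must be strictly increasing"))
    }
    tibble(anchor_id = id, reference_id = as.character(a$reference_id),
           positions = list(pos),
           expected = list(as.character(unlist(a$expected))))
  })
  motifs <- vapply(raw$motifs %||% list(), as.character, character(1))
  structure(list(rules = rules, anchors = anchors, motifs = motifs),
            class = "family_rules")
}

#' Write a family-rule configuration to YAML
#'
#' Inverse of [read_family_rules()].
#'
#' @param rules A `family_rules` object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_family_rules <- function(rules, path) {
  fams <- list()
  for (i in seq_len(nrow(rules$rules))) {
    r <- rules$rules[i, ]
    rd <- r$required_domains[[1]]
    fams[[r$family]] <- list(
      required_domains = stats::setNames(as.list(rd$min_count), rd$domain),
      forbidden_domains = as.list(r$forbidden_domains[[1]]),
      required_motifs = as.list(r$required_motifs[[1]]),
      residue_anchors = as.list(r$residue_anchors[[1]]),
      localization = r$localization,
      classifier = if ("classifier" %in% names(r)) r$classifier else "none",
      report_motifs = if ("report_motifs" %in% names(r))
        as.list(r$report_motifs[[1]]) else list())
  }
  anchors <- list()
  for (i in seq_len(nrow(rules$anchors))) {
    a <- rules$anchors[i, ]
    anchors[[a$anchor_id]] <- list(
      reference_id = a$reference_id,
      positions = as.list(a$positions[[1]]),
      expected = as.list(a$expected[[1]]))
  }
  doc <- list(motifs = as.list(rules$motifs), anchors = anchors,
              families = fams)
  writeLines(yaml::as.yaml(doc), path)
  invisible(path)
}

# 12-column tabular hit-table layout (BLAST outfmt-6 compatible):
# qseqid sseqid pident length mismatch gapopen qstart qend sstart send
# evalue bitscore. Sequence ids are encoded "species|protein_id".
HIT_COLS <- c("query_species", "query_id", "subject_species", "subject_id",
              "identity", "align_length", "mismatches", "gap_opens",
              "q_start", "q_end", "s_start", "s_end", "evalue", "bitscore")

#' Write a hit table in 12-column tabular search format
#'
#' @param hits Hit tibble (see [all_vs_all_hits()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_hit_table <- function(hits, path) {
  df <- tibble(
    qseqid = paste0(hits$query_species, "|", hits$query_id),
    sseqid = paste0(hits$subject_species, "|", hits$subject_id),
    pident = sprintf("%.2f", 100 * hits$identity),
    length = hits$align_length, mismatch = hits$mismatches,
    gapopen = hits$gap_opens, qstart = hits$q_start, qend = hits$q_end,
    sstart = hits$s_start, send = hits$s_end,
    evalue = sprintf("%.3g", hits$evalue),
    bitscore = sprintf("%.1f", hits$bitscore))
  readr::write_tsv(df, path, col_names = FALSE, progress = FALSE)
  invisible(path)
}

#' Read a 12-column tabular hit table
#'
#' Accepts standard tabular output from sequence-search tools (BLAST
#' `-outfmt 6` layout). Ids of the form `species|protein_id` are split; ids
#' without a `|` get species `NA`.
#'
#' @param path Path to the TSV (no header).
#' @return Hit tibble with identity as a fraction in `[0, 1]`.
#' @export
read_hit_table <- function(path) {
  df <- readr::read_tsv(path, col_names = c(
    "qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
    "qstart", "qend", "sstart", "send", "evalue", "bitscore"),
    col_types = "ccdiiiiiiidd", progress = FALSE)
  split_id <- function(x) {
    parts <- stringr::str_split_fixed(x, stringr::fixed("|"), 2)
    has <- nzchar(parts[, 2])
    list(species = ifelse(has, parts[, 1], NA_character_),
         id = ifelse(has, parts[, 2], parts[, 1]))
  }
  q <- split_id(df$qseqid); s <- split_id(df$sseqid)
  tibble(query_species = q$species, query_id = q$id,
         subject_species = s$species, subject_id = s$id,
         identity = df$pident / 100, align_length = df$length,
         mismatches = df$mismatch, gap_opens = df$gapopen,
         q_start = df$qstart, q_end = df$qend, s_start = df$sstart,
         s_end = df$send, evalue = df$evalue, bitscore = df$bitscore)
}

#' Write a copy-number matrix to TSV
#'
#' Species rows, family columns, integer counts.
#'
#' @param cnm Copy-number tibble from [copy_number_matrix()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_copy_number_matrix <- function(cnm, path) {
  readr::write_tsv(cnm, path, progress = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
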