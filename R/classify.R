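STRUCTURAL_PSEUDO_DOMAINS <- c("TM", "LRR", "SIGNAL")

#' Check a protein against a family architecture rule
#'
#' A protein passes when every required domain meets its minimum count, no
#' forbidden domain is present, every required motif is found, and the
#' localization matches the rule's expectation (or the rule says `any`).
#' The pseudo-domain names `TM`, `LRR` and `SIGNAL` are satisfied from the
#' structural profile rather than from PSSM hits.
#'
#' @param rule One-row family-rule tibble (see [read_family_rules()]).
#' @param domain_hits Domain-hit tibble for this protein (`domain` column).
#' @param motif_hits Motif-hit tibble for this protein (`motif_id` column).
#' @param structure One-row structural profile for this protein (see
#'   [predict_structure()]).
#' @param known_domains Character vector of recognised domain names
#'   (PSSM names); rules naming unknown domains raise an error.
#' @return List with `pass` (logical) and `reasons` (character vector of
#'   every failed clause; empty when passing).
#' @export
check_architecture <- function(rule, domain_hits, motif_hits, structure,
                               known_domains = NULL) {
  req <- rule$required_domains[[1]]
  forb <- rule$forbidden_domains[[1]]
  motifs <- rule$required_motifs[[1]]
  if (!is.null(known_domains)) {
    unknown <- setdiff(c(req$domain, forb),
                       c(known_domains, STRUCTURAL_PSEUDO_DOMAINS))
    if (length(unknown)) {
      abort(paste0("rule for family ", rule$family,
                   " names unknown domain(s): ",
                   paste(unknown, collapse = ", ")))
    }
  }
  count_of <- function(d) {
    if (d == "TM") return(structure$n_tm)
    if (d == "LRR") return(structure$n_lrr)
    if (d == "SIGNAL") return(as.integer(structure$signal_peptide))
    sum(domain_hits$domain == d)
  }
  reasons <- character(0)
  for (i in seq_len(nrow(req))) {
    if (count_of(req$domain[i]) < req$min_count[i]) {
      reasons <- c(reasons, paste0(req$domain[i], " absent"))
    }
  }
  for (d in forb) {
    if (count_of(d) > 0) reasons <- c(reasons, paste0(d, " forbidden"))
  }
  for (m in motifs) {
    if (!m %in% motif_hits$motif_id) {
      reasons <- c(reasons, paste0("motif ", m, " absent"))
    }
  }
  if (rule$localization != "any" &&
      structure$localization != rule$localization) {
    reasons <- c(reasons, paste0("localization ", structure$localization,
                                 " != ", rule$localization))
  }
  list(pass = length(reasons) == 0, reasons = reasons)
}

anchored_call <- function(msa, member_id, anchor, family_context) {
  st <- residue_state_at_anchor(msa, member_id, anchor)
  list(protein_id = member_id, family_context = family_context,
       state = if (st$all_expected) "catalytic" else "non-catalytic",
       states = st$states)
}

#' Call amidase (catalytic) state of a peptidoglycan recognition protein
#'
#' Catalytic PGRPs retain the cysteine and two histidines required for
#' zinc binding; proteins that have lost any of the three anchored
#' residues are called non-catalytic. The member is read at the anchored
#' positions of the annotated reference through the alignment; a gap at
#' any anchor position (reported as `-`) is non-catalytic.
#'
#' @param msa Alignment containing the member and the anchor's annotated
#'   reference.
#' @param member_id Member to call.
#' @param anchor Residue anchor for the zinc-binding triad (see
#'   [residue_anchor()]).
#' @return List with `state` (`"catalytic"`/`"non-catalytic"`) and
#'   `states` (per-position letters).
#' @export
pgrp_catalytic_call <- function(msa, member_id, anchor) {
  anchored_call(msa, member_id, anchor, "PGRP")
}

#' Call glucanase activity from the active-site glutamate pair
#'
#' Glucanase-active GH16 proteins hold glutamate at both anchored
#' active-site positions (numbered 188 and 193 on the annotated
#' reference); proteins lacking one or both are flagged as the
#' non-enzymatic (asterisk) class.
#'
#' @inheritParams pgrp_catalytic_call
#' @param anchor Residue anchor for the glutamate pair.
#' @return As [pgrp_catalytic_call()], plus `asterisk` (TRUE when
#'   non-enzymatic).
#' @export
glucanase_activity_call <- function(msa, member_id, anchor) {
  res <- anchored_call(msa, member_id, anchor, "GH16")
  res$asterisk <- res$state == "non-catalytic"
  res
}

#' Classify a thioester-containing protein
#'
#' Scans for the canonical thioester motif `GCGEQ`. Proteins lacking the
#' motif are classed `MCR-like`. The critical cysteine is the C of a found
#' motif; when the motif is absent, the motif region is located with the
#' cysteine position wildcarded (`GXGEQ`) and any cysteine within
#' `cys_window` residues of that site counts.
#'
#' @param sequence Amino-acid string.
#' @param cys_window Fallback search radius around the degenerate motif
#'   site (default 10).
#' @return Tibble with `thioester_motif_present`, `critical_cys_present`,
#'   `class` (`"TEP"` or `"MCR-like"`), `motif_start` (NA when absent).
#' @export
tep_classify <- function(sequence, cys_window = 10) {
  hits <- scan_motif(sequence, compile_degenerate_motif("GCGEQ", "GCGEQ"))
  if (nrow(hits) > 0) {
    return(tibble(thioester_motif_present = TRUE,
                  critical_cys_present = TRUE, class = "TEP",
                  motif_start = hits$start[1]))
  }
  relaxed <- scan_motif(sequence,
                        compile_degenerate_motif("GXGEQ", "GXGEQ"))
  cys_ok <- FALSE
  site <- NA_integer_
  if (nrow(relaxed) > 0) {
    site <- relaxed$start[1] + 1L  # where the critical cysteine would sit
    chars <- strsplit(sequence, "", fixed = TRUE)[[1]]
    lo <- max(1L, site - cys_window)
    hi <- min(length(chars), site + cys_window)
    cys_ok <- any(chars[lo:hi] == "C")
  }
  tibble(thioester_motif_present = FALSE, critical_cys_present = cys_ok,
         class = "MCR-like", motif_start = NA_integer_)
}

#' Classify Toll-like receptor ectodomain structure
#'
#' Single cysteine-cluster receptors (scc) have exactly one ectodomain
#' cluster sitting juxtamembrane; multiple cysteine-cluster receptors
#' (mcc) have exactly two; anything else (no cluster, a single
#' non-juxtamembrane cluster, or more than two clusters) is `atypical`
#' with the count reported. Receptors whose ectodomain is shorter than
#' `min_ectodomain` are flagged truncated.
#'
#' @param structure One-row structural profile (see
#'   [predict_structure()]).
#' @param tir_present Logical: was a TIR domain detected? Calling a
#'   protein without one is an error (not a TLR).
#' @param min_ectodomain Truncation threshold in residues (default 150).
#' @param seq_length Protein length (used when no TM segment exists).
#' @return Tibble with `class` (`scc`/`mcc`/`atypical`), `n_clusters`,
#'   `truncated`.
#' @export
classify_tlr <- function(structure, tir_present, min_ectodomain = 150,
                         seq_length = NULL) {
  if (!isTRUE(tir_present)) abort("no TIR domain: not a TLR")
  cys <- structure$cys_clusters[[1]]
  n <- nrow(cys)
  class <- if (n == 1 && cys$juxtamembrane[1]) "scc"
  else if (n == 2) "mcc"
  else "atypical"
  tm <- structure$tm[[1]]
  ecto_tm <- tm[tm$start > 35, , drop = FALSE]
  ecto_len <- if (nrow(ecto_tm) > 0) min(ecto_tm$start) - 1L
  else seq_length %||% NA_integer_
  tibble(class = class, n_clusters = n,
         truncated = !is.na(ecto_len) && ecto_len < min_ectodomain)
}

#' Check Relish-type NF-kB architecture
#'
#' Relish fuses the Rel homology domain (RHD) with a C-terminal ankyrin
#' repeat region; truncated forms keep the RHD but lack the ankyrins. The
#' ankyrin region requires at least `min_ank` ankyrin-repeat hits located
#' C-terminal of the RHD hit.
#'
#' @param domain_hits Domain-hit tibble for one protein (`domain`,
#'   `start`, `end`).
#' @param rhd_name,ank_name Domain names for the RHD and ankyrin models.
#' @param min_ank Minimum ankyrin hits (default 2).
#' @return Tibble with `has_rhd`, `has_ankyrin_region`.
#' @export
relish_architecture <- function(domain_hits, rhd_name = "RHD",
                                ank_name = "ANK", min_ank = 2) {
  rhd <- domain_hits[domain_hits$domain == rhd_name, , drop = FALSE]
  has_rhd <- nrow(rhd) > 0
  has_ank <- FALSE
  if (has_rhd) {
    rhd_end <- min(rhd$end)
    ank <- domain_hits[domain_hits$domain == ank_name &
                         domain_hits$start > rhd_end, , drop = FALSE]
    has_ank <- nrow(ank) >= min_ank
  }
  tibble(has_rhd = has_rhd, has_ankyrin_region = has_ank)
}

#' Integrate evidence into family assignments
#'
#' Combines the three independent evidence sources — reciprocal best hit
#' to a labelled reference query, orthogroup family label, and
#' profile/motif hits to a family's diagnostic models — into one call per
#' protein. A protein is accepted for the family with the most evidence
#' sources iff it has at least one source, its architecture rule passes,
#' and its best reciprocal reference hit (when one exists) is to a member
#' of that family. Ties between families and reciprocal hits pointing at
#' non-family reference proteins are rejected with a reason.
#'
#' @param proteins Protein tibble.
#' @param rules `family_rules` object.
#' @param rbh Output of [best_reciprocal_hits()].
#' @param orthogroups Output of [cluster_orthogroups()].
#' @param domain_hits Domain-hit tibble over all proteins.
#' @param motif_hits Motif-hit tibble over all proteins.
#' @param structure Structural profile tibble (one row per protein).
#' @param queries Labelled query tibble (`species`, `protein_id`,
#'   `family`) — the reference species' immunity proteins.
#' @param known_domains Recognised PSSM domain names.
#' @return List with `accepted` (annotation tibble: `species`,
#'   `protein_id`, `family`, evidence flags, `functional` list-column) and
#'   `rejected` (tibble with `reason`).
#' @export
integrate_evidence <- function(proteins, rules, rbh, orthogroups,
                               domain_hits, motif_hits, structure, queries,
                               known_domains = NULL) {
  qfam <- stats::setNames(queries$family, queries$protein_id)
  og <- orthogroups
  og_key <- paste0(og$species, "|", og$protein_id)
  accepted <- list(); rejected <- list()
  for (i in seq_len(nrow(proteins))) {
    sp <- proteins$species[i]; pid <- proteins$protein_id[i]
    dh <- domain_hits[domain_hits$species == sp &
                        domain_hits$protein_id == pid, , drop = FALSE]
    mh <- motif_hits[motif_hits$species == sp &
                       motif_hits$protein_id == pid, , drop = FALSE]
    st <- structure[structure$species == sp &
                      structure$protein_id == pid, , drop = FALSE]
    # evidence per family
    ev <- list()
    bump <- function(ev, fam, src) {
      if (is.na(fam)) return(ev)
      ev[[fam]] <- union(ev[[fam]], src); ev
    }
    my_rbh <- rbh[rbh$species == sp & rbh$protein_id == pid, , drop = FALSE]
    rbh_ref_fam <- NA_character_
    if (nrow(my_rbh) == 1) {
      rbh_ref_fam <- unname(qfam[my_rbh$reference_id[1]])
      if (!is.null(rbh_ref_fam) && !is.na(rbh_ref_fam)) {
        ev <- bump(ev, rbh_ref_fam, "rbh")
      }
    }
    my_og <- og[og_key == paste0(sp, "|", pid), , drop = FALSE]
    if (nrow(my_og) == 1 && !my_og$ambiguous[1] && !is.na(my_og$family[1])) {
      ev <- bump(ev, my_og$family[1], "cluster")
    }
    if (!is.na(qfam[pid]) && sp %in% queries$species[queries$protein_id == pid]) {
      ev <- bump(ev, unname(qfam[pid]), "cluster")  # the query itself
    }
    for (j in seq_len(nrow(rules$rules))) {
      r <- rules$rules[j, ]
      profile_doms <- setdiff(r$required_domains[[1]]$domain,
                              STRUCTURAL_PSEUDO_DOMAINS)
      dom_hit <- length(profile_doms) > 0 &&
        all(profile_doms %in% dh$domain)
      motif_hit <- length(r$required_motifs[[1]]) > 0 &&
        all(r$required_motifs[[1]] %in% mh$motif_id)
      if (dom_hit || motif_hit) ev <- bump(ev, r$family, "profile")
    }
    if (length(ev) == 0) next  # background: no evidence, silently skipped
    n_src <- vapply(ev, length, integer(1))
    best <- names(ev)[n_src == max(n_src)]
    if (length(best) > 1) {
      rejected[[length(rejected) + 1]] <- tibble(
        species = sp, protein_id = pid, family = NA_character_,
        reason = paste0("ambiguous evidence tie between families: ",
                        paste(sort(best), collapse = ", ")))
      next
    }
    fam <- best
    rule <- rules$rules[rules$rules$family == fam, , drop = FALSE]
    arch <- check_architecture(rule, dh, mh, st, known_domains)
    if (!arch$pass) {
      rejected[[length(rejected) + 1]] <- tibble(
        species = sp, protein_id = pid, family = fam,
        reason = paste(arch$reasons, collapse = "; "))
      next
    }
    if (nrow(my_rbh) == 1 &&
        (is.na(rbh_ref_fam) || rbh_ref_fam != fam)) {
      rejected[[length(rejected) + 1]] <- tibble(
        species = sp, protein_id = pid, family = fam,
        reason = paste0("reciprocal best reference hit (",
                        my_rbh$reference_id[1], ") is not a ", fam,
                        " family member"))
      next
    }
    accepted[[length(accepted) + 1]] <- tibble(
      species = sp, protein_id = pid, family = fam,
      rbh = "rbh" %in% ev[[fam]],
      cluster = "cluster" %in% ev[[fam]],
      profile = "profile" %in% ev[[fam]],
      architecture = TRUE,
      functional = list(c(localization = st$localization)))
  }
  acc <- if (length(accepted)) bind_rows(accepted) else
    tibble(species = character(0), protein_id = character(0),
           family = character(0), rbh = logical(0), cluster = logical(0),
           profile = logical(0), architecture = logical(0),
           functional = list())
  rej <- if (length(rejected)) bind_rows(rejected) else
    tibble(species = character(0), protein_id = character(0),
           family = character(0), reason = character(0))
  list(accepted = acc, rejected = rej)
}

#' Tabulate immunity-gene copy numbers
#'
#' Exact per-(species, family) counts of accepted annotation records,
#' zero-filled over the full species-by-family grid.
#'
#' @param accepted Accepted annotation tibble.
#' @param species Character vector of all species (rows).
#' @param families Character vector of all families (columns).
#' @return Tibble with a `species` column and one integer column per
#'   family, species in the given order.
#' @export
copy_number_matrix <- function(accepted,
                               species = sort(unique(accepted$species)),
                               families = sort(unique(accepted$family))) {
  grid <- tidyr::expand_grid(species = species, family = families)
  counts <- accepted %>%
    dplyr::count(.data$species, .data$family, name = "n")
  full <- grid %>%
    left_join(counts, by = c("species", "family")) %>%
    mutate(n = tidyr::replace_na(.data$n, 0L))
  out <- tidyr::pivot_wider(full, names_from = "family",
                            values_from = "n")
  out[match(species, out$species), , drop = FALSE]
}
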