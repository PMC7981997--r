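#' @title Drug-likeness rule systems and the candidate-compound gate
#'
#' @description
#' Five descriptor-threshold rule systems (Lipinski, Ghose, Veber, Egan,
#' Muegge) plus the Abbott bioavailability score, combined into the
#' screening gate used for herbal-compound triage: a compound is retained
#' when it satisfies at least `min_rules_passed` of the five rule systems
#' and its bioavailability score is at least `min_bas`.
#'
#' Thresholds follow the SwissADME implementations of the published rules:
#' Lipinski uses MLOGP, Ghose and Egan use WLOGP, Muegge uses XLOGP3.
#' All range bounds are inclusive except where a rule states a strict
#' inequality (Muegge requires carbons > 4 and heteroatoms > 1).
#'
#' @name chem_filter
NULL

# Descriptor columns every evaluator may touch; used for NA diagnostics.
.descriptor_cols <- c(
  "mw", "mlogp", "wlogp", "xlogp", "hbd", "hba", "tpsa",
  "rotatable_bonds", "molar_refractivity", "heavy_atoms",
  "rings", "carbons", "heteroatoms"
)

.check_descriptors <- function(d, cols) {
  missing_cols <- setdiff(cols, names(d))
  if (length(missing_cols) > 0L) {
    stop("missing descriptor column(s): ", paste(missing_cols, collapse = ", "))
  }
  for (col in cols) {
    bad <- which(!is.finite(as.numeric(d[[col]])))
    if (length(bad) > 0L) {
      stop(sprintf(
        "missing or non-finite descriptor '%s' in record(s) %s",
        col, paste(bad, collapse = ", ")
      ))
    }
  }
  invisible(TRUE)
}

#' Lipinski rule of five (MLOGP variant)
#'
#' Counts violations among mw > 500, MLOGP > 4.15, H-bond donors > 5 and
#' H-bond acceptors > 10; at most one violation is tolerated.
#'
#' @param d data frame with columns `mw`, `mlogp`, `hbd`, `hba`.
#' @return list with integer vector `violations` (0--4) and logical `passed`.
#' @export
evaluate_lipinski <- function(d) {
  .check_descriptors(d, c("mw", "mlogp", "hbd", "hba"))
  violations <- (d$mw > 500) + (d$mlogp > 4.15) + (d$hbd > 5) + (d$hba > 10)
  list(violations = as.integer(violations), passed = violations <= 1)
}

#' Ghose filter
#'
#' 160 <= mw <= 480, -0.4 <= WLOGP <= 5.6, 40 <= molar refractivity <= 130,
#' 20 <= heavy atoms <= 70 (all inclusive).
#'
#' @param d data frame with columns `mw`, `wlogp`, `molar_refractivity`,
#'   `heavy_atoms`.
#' @return logical vector.
#' @export
evaluate_ghose <- function(d) {
  .check_descriptors(d, c("mw", "wlogp", "molar_refractivity", "heavy_atoms"))
  d$mw >= 160 & d$mw <= 480 &
    d$wlogp >= -0.4 & d$wlogp <= 5.6 &
    d$molar_refractivity >= 40 & d$molar_refractivity <= 130 &
    d$heavy_atoms >= 20 & d$heavy_atoms <= 70
}

#' Veber filter
#'
#' Rotatable bonds <= 10 and TPSA <= 140 A^2.
#'
#' @param d data frame with columns `rotatable_bonds`, `tpsa`.
#' @return logical vector.
#' @export
evaluate_veber <- function(d) {
  .check_descriptors(d, c("rotatable_bonds", "tpsa"))
  d$rotatable_bonds <= 10 & d$tpsa <= 140
}

#' Egan filter
#'
#' WLOGP <= 5.88 and TPSA <= 131.6 A^2.
#'
#' @param d data frame with columns `wlogp`, `tpsa`.
#' @return logical vector.
#' @export
evaluate_egan <- function(d) {
  .check_descriptors(d, c("wlogp", "tpsa"))
  d$wlogp <= 5.88 & d$tpsa <= 131.6
}

#' Muegge filter
#'
#' 200 <= mw <= 600, -2 <= XLOGP3 <= 5, TPSA <= 150, rings <= 7,
#' carbons > 4 (strict), heteroatoms > 1 (strict), rotatable bonds <= 15,
#' H-bond acceptors <= 10, H-bond donors <= 5.
#'
#' @param d data frame with columns `mw`, `xlogp`, `tpsa`, `rings`,
#'   `carbons`, `heteroatoms`, `rotatable_bonds`, `hba`, `hbd`.
#' @return logical vector.
#' @export
evaluate_muegge <- function(d) {
  .check_descriptors(d, c(
    "mw", "xlogp", "tpsa", "rings", "carbons", "heteroatoms",
    "rotatable_bonds", "hba", "hbd"
  ))
  d$mw >= 200 & d$mw <= 600 &
    d$xlogp >= -2 & d$xlogp <= 5 &
    d$tpsa <= 150 &
    d$rings <= 7 &
    d$carbons > 4 &
    d$heteroatoms > 1 &
    d$rotatable_bonds <= 15 &
    d$hba <= 10 &
    d$hbd <= 5
}

#' Abbott bioavailability score
#'
#' Discrete probability class for >10% oral bioavailability, assigned from
#' the ionization class at physiological pH, TPSA and rule-of-five
#' compliance (Martin's decision tree): anions score by TPSA
#' (<= 75 -> 0.85; (75, 150] -> 0.56; > 150 -> 0.11), everything else
#' scores by Lipinski compliance (passed -> 0.55, failed -> 0.17).
#'
#' @param d data frame with columns `ionization_class` (one of "anion",
#'   "cation", "neutral", "zwitterion"), `tpsa`, and the Lipinski
#'   descriptor columns.
#' @param unknown_ionization what to do with an unrecognised ionization
#'   class: "neutral" (default; treat as non-anion with a warning) or
#'   "error".
#' @return numeric vector taking values in \{0.11, 0.17, 0.55, 0.56, 0.85\}.
#' @export
abbott_bioavailability_score <- function(d, unknown_ionization = c("neutral", "error")) {
  unknown_ionization <- match.arg(unknown_ionization)
  .check_descriptors(d, c("tpsa", "mw", "mlogp", "hbd", "hba"))
  ion <- as.character(d$ionization_class)
  known <- c("anion", "cation", "neutral", "zwitterion")
  bad <- which(is.na(ion) | !(ion %in% known))
  if (length(bad) > 0L) {
    if (unknown_ionization == "error") {
      stop("unknown ionization class in record(s) ", paste(bad, collapse = ", "))
    }
    warning(
      "unknown ionization class in record(s) ",
      paste(bad, collapse = ", "), "; treated as neutral"
    )
    ion[bad] <- "neutral"
  }
  lip <- evaluate_lipinski(d)$passed
  score <- ifelse(lip, 0.55, 0.17)
  anion <- ion == "anion"
  score[anion & d$tpsa <= 75] <- 0.85
  score[anion & d$tpsa > 75 & d$tpsa <= 150] <- 0.56
  score[anion & d$tpsa > 150] <- 0.11
  score
}

#' Screen a compound descriptor table through the drug-likeness gate
#'
#' Evaluates all five rule systems and the Abbott bioavailability score per
#' compound and flags the compounds that satisfy the candidate gate:
#' at least `min_rules_passed` rules passed and bioavailability score
#' >= `min_bas`. Input order is preserved.
#'
#' @param descriptors data frame with one row per compound: `compound_id`,
#'   optionally `name`, the descriptor columns (see [evaluate_muegge()] et
#'   al.) and `ionization_class`.
#' @param min_rules_passed minimum number of rule systems passed (default 2).
#' @param min_bas minimum Abbott bioavailability score (default 0.30).
#' @return data frame of verdicts: `compound_id`, per-rule logical columns
#'   `lipinski`, `ghose`, `veber`, `egan`, `muegge`, `lipinski_violations`,
#'   `bioavailability_score`, `rules_passed`, `selected`.
#' @export
select_candidates <- function(descriptors, min_rules_passed = 2, min_bas = 0.30) {
  stopifnot(is.data.frame(descriptors))
  if (!"compound_id" %in% names(descriptors)) {
    stop("descriptor table must have a 'compound_id' column")
  }
  ids <- as.character(descriptors$compound_id)
  dup <- unique(ids[duplicated(ids)])
  if (length(dup) > 0L) {
    stop("duplicate compound_id(s): ", paste(dup, collapse = ", "))
  }
  .check_descriptors(descriptors, .descriptor_cols)

  lip <- evaluate_lipinski(descriptors)
  rules <- data.frame(
    lipinski = lip$passed,
    ghose = evaluate_ghose(descriptors),
    veber = evaluate_veber(descriptors),
    egan = evaluate_egan(descriptors),
    muegge = evaluate_muegge(descriptors)
  )
  bas <- abbott_bioavailability_score(descriptors)
  rules_passed <- as.integer(rowSums(rules))
  data.frame(
    compound_id = ids,
    rules,
    lipinski_violations = lip$violations,
    bioavailability_score = bas,
    rules_passed = rules_passed,
    selected = rules_passed >= min_rules_passed & bas >= min_bas,
    stringsAsFactors = FALSE
  )
}
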