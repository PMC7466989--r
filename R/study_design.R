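#' @keywords internal
"_PACKAGE"

# non-standard-evaluation column names used in ggplot2 aesthetics
utils::globalVariables(c("level", "blup", "lower", "upper", "x", "y", "r"))

## Canonical column layout for animal-level study tables -----------------

design_columns <- function() {
  c("animal_id", "dam_strain", "sire_strain", "sex", "treatment",
    "batch", "cage")
}

phenotype_columns <- function() {
  c("distance_pre", "distance_post", "vertical_pre", "vertical_post",
    "stereotypy_pre", "stereotypy_post", "centroid_pre", "centroid_post",
    "eps_pre", "eps_post", "weight_pre", "weight_post",
    "vcm_subtle", "vcm_overt", "vcm_tongue", "vcm_tremor", "plasma")
}

#' Canonical random-effect names, in their fixed order
#'
#' The five random effects of the full model: batch, strain,
#' strain-by-treatment, strain-by-sex, and strain-by-sex-by-treatment.
#' All functions that take an `effects` argument expect a subset of this
#' vector.
#'
#' @return Character vector of the five effect names.
#' @export
rix_effects <- function() {
  c("batch", "strain", "strain_x_tmt", "strain_x_sex", "strain_x_sex_x_tmt")
}

rix_abort <- function(message, class) {
  stop(structure(class = c(class, "rixmm_error", "error", "condition"),
                 list(message = message, call = sys.call(-1))))
}

## AnimalTable ------------------------------------------------------------

#' Construct an animal table from an in-memory data frame
#'
#' Validates an animal-level study table (one row per mouse) and wraps it
#' with its strain and batch universes.  Validation enforces: unique
#' `animal_id`; `dam_strain != sire_strain`; `sex` in female/male;
#' `treatment` in placebo/haloperidol; EPS latencies within \[0, 60\] s;
#' VCM counts non-negative integers; positive body weights; and plasma
#' concentration present only for haloperidol-treated animals.
#' Cage-pairing (at most one animal per treatment arm per cage) is checked
#' and reported in the metadata, but not enforced.
#'
#' @param df Data frame with the canonical columns (see
#'   [load_animal_table()] for the layout).  Missing phenotype columns are
#'   added as `NA`.
#' @param source Character label recorded in the metadata.
#' @return An object of class `animal_table`: a list with `records`
#'   (validated data frame, row order preserved), `strain_universe`,
#'   `batch_universe`, and `metadata`.
#' @export
as_animal_table <- function(df, source = "in-memory") {
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  missing_cols <- setdiff(design_columns(), names(df))
  if (length(missing_cols) > 0L) {
    rix_abort(sprintf("required column(s) missing: %s",
                      paste(missing_cols, collapse = ", ")),
              "rixmm_schema_error")
  }
  for (col in setdiff(phenotype_columns(), names(df))) df[[col]] <- NA_real_
  for (col in c("animal_id", "dam_strain", "sire_strain", "sex",
                "treatment", "batch", "cage")) {
    df[[col]] <- as.character(df[[col]])
  }
  for (col in phenotype_columns()) df[[col]] <- as.numeric(df[[col]])

  if (anyDuplicated(df$animal_id)) {
    dup <- unique(df$animal_id[duplicated(df$animal_id)])
    rix_abort(sprintf("duplicate animal_id: %s",
                      paste(utils::head(dup, 5L), collapse = ", ")),
              "rixmm_integrity_error")
  }
  if (any(df$dam_strain == df$sire_strain)) {
    rix_abort("dam_strain equals sire_strain for at least one animal (RIX lines are crosses of two distinct strains)",
              "rixmm_integrity_error")
  }
  bad_sex <- setdiff(unique(df$sex), c("female", "male"))
  if (length(bad_sex) > 0L) {
    rix_abort(sprintf("sex must be 'female' or 'male'; found: %s",
                      paste(bad_sex, collapse = ", ")),
              "rixmm_schema_error")
  }
  bad_tmt <- setdiff(unique(df$treatment), c("placebo", "haloperidol"))
  if (length(bad_tmt) > 0L) {
    rix_abort(sprintf("treatment must be 'placebo' or 'haloperidol'; found: %s",
                      paste(bad_tmt, collapse = ", ")),
              "rixmm_schema_error")
  }
  eps <- c(df$eps_pre, df$eps_post)
  if (any(eps < 0 | eps > 60, na.rm = TRUE)) {
    rix_abort("EPS latency outside [0, 60] s (assay ceiling is 60 s)",
              "rixmm_range_error")
  }
  vcm <- as.matrix(df[, c("vcm_subtle", "vcm_overt", "vcm_tongue", "vcm_tremor")])
  if (any(vcm < 0, na.rm = TRUE) ||
      any(abs(vcm - round(vcm)) > 1e-8, na.rm = TRUE)) {
    rix_abort("VCM counts must be non-negative integers", "rixmm_range_error")
  }
  wt <- c(df$weight_pre, df$weight_post)
  if (any(wt <= 0, na.rm = TRUE)) {
    rix_abort("body weights must be positive", "rixmm_range_error")
  }
  if (any(!is.na(df$plasma) & df$treatment == "placebo")) {
    rix_abort("plasma concentration recorded for a placebo-treated animal",
              "rixmm_integrity_error")
  }

  df$rix_line <- paste0(df$dam_strain, "x", df$sire_strain)

  ## cage-pairing diagnostic: a cage should hold one animal per arm
  cage_tab <- table(df$cage, df$treatment)
  bad_cages <- rownames(cage_tab)[apply(cage_tab, 1L, max) > 1L]

  strain_universe <- sort(unique(c(df$dam_strain, df$sire_strain)))
  batch_universe <- sort(unique(df$batch))

  structure(
    list(records = df,
         strain_universe = strain_universe,
         batch_universe = batch_universe,
         metadata = list(
           source = source,
           n = nrow(df),
           n_by_arm = table(df$treatment),
           n_by_sex = table(df$sex),
           n_lines = length(unique(df$rix_line)),
           cages_violating_pairing = bad_cages)),
    class = "animal_table")
}

#' Read an animal-level study table from CSV
#'
#' Reads a CSV with one row per animal, optionally remapping column names so
#' that an external export (for example a phenotype-database download) can be
#' consumed without editing the file.  Empty cells become missing values and
#' are preserved as such, never converted to zero.  Row order is preserved.
#'
#' Required design columns (canonical names): `animal_id`, `dam_strain`,
#' `sire_strain`, `sex` (female/male), `treatment` (placebo/haloperidol),
#' `batch`, `cage`.  Recognised phenotype columns: `distance_pre/post`,
#' `vertical_pre/post`, `stereotypy_pre/post`, `centroid_pre/post`,
#' `eps_pre/post`, `weight_pre/post`, `vcm_subtle`, `vcm_overt`,
#' `vcm_tongue`, `vcm_tremor`, `plasma`.
#'
#' @param path Path to a CSV file with a header row.
#' @param schema Optional named character vector mapping canonical column
#'   names to the names used in the file, e.g.
#'   `c(animal_id = "MouseID", dam_strain = "Dam")`.
#' @return An [as_animal_table()] object.
#' @export
load_animal_table <- function(path, schema = NULL) {
  if (!file.exists(path)) {
    rix_abort(sprintf("input file not found: %s", path), "rixmm_io_error")
  }
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        na.strings = c("", "NA"), check.names = FALSE)
  if (!is.null(schema)) {
    for (canonical in names(schema)) {
      file_col <- schema[[canonical]]
      if (!file_col %in% names(df)) {
        rix_abort(sprintf("schema maps '%s' to '%s', which is not in the file",
                          canonical, file_col), "rixmm_schema_error")
      }
      names(df)[names(df) == file_col] <- canonical
    }
  }
  as_animal_table(df, source = path)
}

#' @export
print.animal_table <- function(x, ...) {
  cat(sprintf("animal_table: %d animals, %d RIX lines, %d parental strains, %d batches\n",
              nrow(x$records), x$metadata$n_lines,
              length(x$strain_universe), length(x$batch_universe)))
  cat("  by arm:", paste(names(x$metadata$n_by_arm), x$metadata$n_by_arm,
                         sep = "=", collapse = ", "), "\n")
  cat("  by sex:", paste(names(x$metadata$n_by_sex), x$metadata$n_by_sex,
                         sep = "=", collapse = ", "), "\n")
  nbad <- length(x$metadata$cages_violating_pairing)
  if (nbad > 0L) {
    cat(sprintf("  note: %d cage(s) violate one-animal-per-arm pairing\n", nbad))
  }
  invisible(x)
}

## RandomDesign -----------------------------------------------------------

interaction_labels <- function(strain, fac) paste(strain, fac, sep = ":")

## membership levels for one row and one effect; returns label vector
row_levels <- function(effect, dam, sire, sex, tmt, batch) {
  switch(effect,
    batch = batch,
    strain = c(dam, sire),
    strain_x_tmt = interaction_labels(c(dam, sire), tmt),
    strain_x_sex = interaction_labels(c(dam, sire), sex),
    strain_x_sex_x_tmt = interaction_labels(c(dam, sire), paste(sex, tmt, sep = ":")),
    rix_abort(sprintf("unknown effect: %s", effect), "rixmm_schema_error"))
}

#' Build multiple-membership random-effect incidence matrices
#'
#' Constructs one 0/1 (or 0/`parent_weight`) incidence matrix per requested
#' random effect.  Each animal belongs to exactly one batch and to the two
#' parental strains of its RIX line, so batch rows sum to 1 and
#' strain-effect rows sum to 2 (or `2 * parent_weight`).  Interaction
#' effects are coded as level expansions: one column per observed
#' (strain, level) combination, with the animal incident on the columns
#' matching its own treatment arm and/or sex.  Unobserved levels are
#' dropped (recorded in the `dropped_levels` attribute); column order is
#' lexicographic for determinism, row order equals record order.
#'
#' @param table An [as_animal_table()] object.
#' @param effects Character subset of [rix_effects()].
#' @param parent_weight Incidence contributed to each of the two parental
#'   strain columns; 1 (default) codes additive parental effects, 0.5 an
#'   average-parent convention.
#' @param interaction_coding `"expanded"` (default; one column per
#'   strain-by-level combination) or `"indicator"` (the strain incidence
#'   multiplied by the 0/1 arm or sex indicator, one column per strain).
#' @return An object of class `random_design`: list with `Z` (named list of
#'   incidence matrices with column labels), `q` (columns per effect),
#'   `effects`, and `animal_id`.
#' @export
build_random_design <- function(table, effects = rix_effects(),
                                parent_weight = 1,
                                interaction_coding = c("expanded", "indicator")) {
  stopifnot(inherits(table, "animal_table"))
  interaction_coding <- match.arg(interaction_coding)
  df <- table$records
  if (nrow(df) == 0L) rix_abort("empty animal table", "rixmm_schema_error")
  if (length(effects) == 0L) rix_abort("empty effect list", "rixmm_schema_error")
  unknown <- setdiff(effects, rix_effects())
  if (length(unknown) > 0L) {
    rix_abort(sprintf("unknown effect(s): %s", paste(unknown, collapse = ", ")),
              "rixmm_schema_error")
  }
  ## keep the canonical effect order 1-5
  effects <- rix_effects()[rix_effects() %in% effects]

  n <- nrow(df)
  Z <- vector("list", length(effects))
  names(Z) <- effects
  dropped <- list()

  for (effect in effects) {
    memb <- lapply(seq_len(n), function(r) {
      row_levels(effect, df$dam_strain[r], df$sire_strain[r],
                 df$sex[r], df$treatment[r], df$batch[r])
    })
    if (effect == "batch") {
      levels_all <- table$batch_universe
    } else if (effect == "strain" || interaction_coding == "indicator") {
      levels_all <- table$strain_universe
    } else {
      fac_levels <- switch(effect,
        strain_x_tmt = c("placebo", "haloperidol"),
        strain_x_sex = c("female", "male"),
        strain_x_sex_x_tmt = as.vector(outer(c("female", "male"),
                                             c("placebo", "haloperidol"),
                                             paste, sep = ":")))
      levels_all <- sort(as.vector(outer(table$strain_universe, sort(fac_levels),
                                         paste, sep = ":")))
    }
    levels_all <- sort(levels_all)
    Zj <- matrix(0, n, length(levels_all),
                 dimnames = list(df$animal_id, levels_all))
    w <- if (effect == "batch") 1 else parent_weight
    for (r in seq_len(n)) {
      lv <- memb[[r]]
      if (effect != "batch" && interaction_coding == "indicator" &&
          effect != "strain") {
        ## indicator coding: strain columns scaled by the 0/1 factor value
        ind <- switch(effect,
          strain_x_tmt = as.numeric(df$treatment[r] == "haloperidol"),
          strain_x_sex = as.numeric(df$sex[r] == "male"),
          strain_x_sex_x_tmt = as.numeric(df$treatment[r] == "haloperidol" &
                                            df$sex[r] == "male"))
        Zj[r, c(df$dam_strain[r], df$sire_strain[r])] <-
          Zj[r, c(df$dam_strain[r], df$sire_strain[r])] + w * ind
      } else {
        for (l in lv) Zj[r, l] <- Zj[r, l] + w
      }
    }
    zero_cols <- colSums(abs(Zj)) == 0
    if (any(zero_cols)) {
      dropped[[effect]] <- colnames(Zj)[zero_cols]
      Zj <- Zj[, !zero_cols, drop = FALSE]
    }
    Z[[effect]] <- Zj
  }

  structure(
    list(Z = Z, q = vapply(Z, ncol, integer(1L)), effects = effects,
         animal_id = df$animal_id, parent_weight = parent_weight,
         interaction_coding = interaction_coding,
         dropped_levels = dropped),
    class = "random_design")
}

#' @export
print.random_design <- function(x, ...) {
  cat(sprintf("random_design: %d animals, %d effect(s)\n",
              length(x$animal_id), length(x$effects)))
  for (e in x$effects) cat(sprintf("  %-20s q = %d\n", e, x$q[[e]]))
  invisible(x)
}

#' Summarise a random design against its source table
#'
#' @param design A [build_random_design()] object.
#' @param table The [as_animal_table()] object the design was built from.
#' @return A list with the per-effect column counts, the number of RIX
#'   lines, per-strain animal counts by arm and sex, per-strain line usage,
#'   batch sizes, and cage-pairing diagnostics.
#' @export
design_report <- function(design, table) {
  stopifnot(inherits(design, "random_design"), inherits(table, "animal_table"))
  df <- table$records
  if (!identical(design$animal_id, df$animal_id)) {
    rix_abort("design was not built from this table (animal ids differ)",
              "rixmm_integrity_error")
  }
  strain_arm <- matrix(0L, length(table$strain_universe), 2L,
                       dimnames = list(table$strain_universe,
                                       c("placebo", "haloperidol")))
  strain_sex <- matrix(0L, length(table$strain_universe), 2L,
                       dimnames = list(table$strain_universe,
                                       c("female", "male")))
  lines_per_strain <- stats::setNames(integer(length(table$strain_universe)),
                                      table$strain_universe)
  line_parents <- unique(df[, c("rix_line", "dam_strain", "sire_strain")])
  for (i in seq_len(nrow(line_parents))) {
    lines_per_strain[line_parents$dam_strain[i]] <-
      lines_per_strain[line_parents$dam_strain[i]] + 1L
    lines_per_strain[line_parents$sire_strain[i]] <-
      lines_per_strain[line_parents$sire_strain[i]] + 1L
  }
  for (r in seq_len(nrow(df))) {
    s <- c(df$dam_strain[r], df$sire_strain[r])
    strain_arm[s, df$treatment[r]] <- strain_arm[s, df$treatment[r]] + 1L
    strain_sex[s, df$sex[r]] <- strain_sex[s, df$sex[r]] + 1L
  }
  out <- list(q = design$q,
       n_animals = nrow(df),
       n_lines = length(unique(df$rix_line)),
       rix_lines = sort(unique(df$rix_line)),
       lines_per_strain = lines_per_strain,
       strain_by_arm = strain_arm,
       strain_by_sex = strain_sex,
       batch_sizes = table(df$batch),
       cages_violating_pairing = table$metadata$cages_violating_pairing,
       dropped_levels = design$dropped_levels)
  structure(out, class = "design_summary")
}

#' Write a design report to disk
#'
#' Writes the per-strain count tables and batch sizes as CSV, the full
#' report as JSON, and (optionally) each incidence matrix in MatrixMarket
#' format for external inspection.
#'
#' @param report A [design_report()] result.
#' @param dir Output directory (created if needed).
#' @param design Optional [build_random_design()] object; when supplied
#'   together with `mtx = TRUE`, each incidence matrix is dumped as
#'   `Z_<effect>.mtx` (requires the Matrix package).
#' @param mtx Write MatrixMarket dumps of the incidence matrices.
#' @return Invisibly, the paths written.
#' @export
write_design_report <- function(report, dir, design = NULL, mtx = FALSE) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0L)
  p <- file.path(dir, "strain_counts.csv")
  utils::write.csv(data.frame(strain = rownames(report$strain_by_arm),
                              report$strain_by_arm, report$strain_by_sex,
                              n_lines = report$lines_per_strain,
                              check.names = FALSE),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "batch_sizes.csv")
  utils::write.csv(data.frame(batch = names(report$batch_sizes),
                              n = as.integer(report$batch_sizes)),
                   p, row.names = FALSE)
  paths <- c(paths, p)
  p <- file.path(dir, "design_report.json")
  jsonlite::write_json(unclass(report), p, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, force = TRUE)
  paths <- c(paths, p)
  if (mtx) {
    if (is.null(design)) {
      rix_abort("mtx = TRUE requires the design object", "rixmm_schema_error")
    }
    if (!requireNamespace("Matrix", quietly = TRUE)) {
      rix_abort("MatrixMarket dumps require the Matrix package",
                "rixmm_dependency_error")
    }
    for (e in design$effects) {
      p <- file.path(dir, sprintf("Z_%s.mtx", e))
      Matrix::writeMM(Matrix::Matrix(design$Z[[e]], sparse = TRUE), p)
      paths <- c(paths, p)
    }
  }
  invisible(paths)
}
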