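# Plain-TSV file formats: linkage map (group/marker/position_cM), offspring
# genotypes (id + one column of 13/14/23/24 codes per marker), phenotypes
# (id/value), and a flat results table mirroring the per-QTL-pair report.
# All writes are atomic (temp file + rename).

.write_tsv_atomic <- function(df, path) {
  tmp <- tempfile(tmpdir = dirname(path), fileext = ".tmp")
  readr::write_tsv(df, tmp, na = "NA", progress = FALSE)
  if (!file.rename(tmp, path)) {
    file.copy(tmp, path, overwrite = TRUE)
    unlink(tmp)
  }
  invisible(path)
}

#' Read a full-sib family dataset from TSV files
#'
#' Reads and cross-validates the three input files: the linkage map
#' (columns `group`, `marker`, `position_cM`), the genotype table (column
#' `id` then one column per marker with cells in `13/14/23/24`), and the
#' phenotype table (`id`, `value`).  Offspring order follows the phenotype
#' file.
#'
#' @param map_path,geno_path,pheno_path File paths.
#' @return An `fs_family` object (see [simulate_family()]), without truth.
#' @export
read_family <- function(map_path, geno_path, pheno_path) {
  map <- readr::read_tsv(map_path, show_col_types = FALSE,
                         col_types = readr::cols(
                           group = "c", marker = "c", position_cM = "d"))
  if (!all(c("group", "marker", "position_cM") %in% names(map)))
    stop("map file must have columns group, marker, position_cM",
         call. = FALSE)
  map <- tibble::tibble(group = map$group, marker = map$marker,
                        position = map$position_cM)
  if (anyDuplicated(map$marker))
    stop("duplicate marker name in map: ",
         map$marker[duplicated(map$marker)][1], call. = FALSE)
  for (g in unique(map$group)) {
    p <- map$position[map$group == g]
    if (is.unsorted(p, strictly = TRUE)) {
      bad <- which(map$group == g)[which(diff(p) <= 0)[1] + 1L]
      stop("map not sorted: position must increase strictly within group '",
           g, "' (line ", bad + 1L, ")", call. = FALSE)
    }
  }

  geno <- readr::read_tsv(geno_path, show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
  if (names(geno)[1] != "id")
    stop("genotype file must start with an 'id' column", call. = FALSE)
  missing_markers <- setdiff(map$marker, names(geno))
  if (length(missing_markers))
    stop("markers in map but not in genotype file: ",
         paste(missing_markers, collapse = ", "), call. = FALSE)
  geno <- geno[, c("id", map$marker)]
  codes <- as.matrix(geno[, -1])
  bad <- which(is.na(codes) | !(codes %in% genotype_labels()), arr.ind = TRUE)
  if (nrow(bad) > 0)
    stop("invalid genotype code '", codes[bad[1, 1], bad[1, 2]],
         "' at row ", bad[1, 1] + 1L, " (offspring ", geno$id[bad[1, 1]],
         "), column ", map$marker[bad[1, 2]], call. = FALSE)

  pheno <- readr::read_tsv(pheno_path, show_col_types = FALSE,
                           col_types = readr::cols(id = "c", value = "d"))
  if (!all(c("id", "value") %in% names(pheno)))
    stop("phenotype file must have columns id, value", call. = FALSE)
  if (any(!is.finite(pheno$value)))
    stop("non-finite phenotype value at line ",
         which(!is.finite(pheno$value))[1] + 1L, call. = FALSE)
  if (!setequal(pheno$id, geno$id))
    stop("id mismatch between genotype and phenotype files (e.g. '",
         c(setdiff(pheno$id, geno$id), setdiff(geno$id, pheno$id))[1],
         "')", call. = FALSE)
  geno <- geno[match(pheno$id, geno$id), ]

  structure(list(map = map, geno = geno, pheno = pheno, truth = NULL),
            class = "fs_family")
}

#' Write a full-sib family dataset as TSV files
#'
#' Writes `map.tsv`, `geno.tsv` and `pheno.tsv` into `dir`; with
#' `truth = TRUE` and simulated data, also `truth.tsv` (per-offspring true
#' QTL genotypes) and `truth_meta.tsv` (positions, `sigma2`, `h2`, seed).
#'
#' @param family An `fs_family` object.
#' @param dir Output directory (created if needed).
#' @param truth Also write the simulation truth, if present.
#' @return The directory path, invisibly.
#' @export
write_family <- function(family, dir, truth = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  .write_tsv_atomic(
    tibble::tibble(group = family$map$group, marker = family$map$marker,
                   position_cM = family$map$position),
    file.path(dir, "map.tsv"))
  .write_tsv_atomic(family$geno, file.path(dir, "geno.tsv"))
  .write_tsv_atomic(family$pheno, file.path(dir, "pheno.tsv"))
  if (truth && !is.null(family$truth)) {
    tr <- family$truth
    .write_tsv_atomic(
      tibble::tibble(id = family$pheno$id, qtl_genotype = tr$genotype),
      file.path(dir, "truth.tsv"))
    .write_tsv_atomic(
      tibble::tibble(
        key = c("qtl1_group", "qtl1_pos", "qtl2_group", "qtl2_pos",
                "sigma2", "h2", "seed"),
        value = as.character(c(tr$qtl1$group, tr$qtl1$pos, tr$qtl2$group,
                               tr$qtl2$pos, tr$sigma2, tr$h2,
                               tr$seed %||% NA))),
      file.path(dir, "truth_meta.tsv"))
  }
  invisible(dir)
}

.result_columns <- function() {
  c("group1", "pos1_cM", "group2", "pos2_cM", "LR", "LR_threshold",
    effect_names(), "sigma2",
    paste0("lr_", setdiff(effect_names(), "mu")))
}

#' Build, write and read the per-QTL-pair results table
#'
#' One row per reported QTL pair: positions, scan LR, permutation
#' threshold, the 16 genetic-effect estimates, the residual variance, and
#' the 15 effect-test LR statistics (38 columns).  Numeric values are
#' serialised with 6 significant digits; unavailable entries are `NA`.
#'
#' @param scan An `fs_scan` object.
#' @param threshold Optional: an `fs_perm` object or a number.
#' @param tests Optional: an [effect_tests()] tibble.
#' @return `result_row()`: a one-row tibble with the 38 result columns.
#' @export
result_row <- function(scan, threshold = NULL, tests = NULL) {
  stopifnot(inherits(scan, "fs_scan"))
  eff <- tidy(scan$best_fit)
  row <- c(
    list(group1 = scan$best$group1, pos1_cM = scan$best$pos1,
         group2 = scan$best$group2, pos2_cM = scan$best$pos2,
         LR = scan$best$lr,
         LR_threshold = if (is.null(threshold)) NA_real_ else
           if (inherits(threshold, "fs_perm")) threshold$threshold else
             as.numeric(threshold)),
    setNames(as.list(eff$value), eff$effect),
    list(sigma2 = scan$best_fit$sigma2)
  )
  lrcols <- setNames(rep(list(NA_real_), 15),
                     paste0("lr_", setdiff(effect_names(), "mu")))
  if (!is.null(tests))
    lrcols[paste0("lr_", tests$effect)] <- as.list(tests$lr)
  tibble::as_tibble(c(row, lrcols))
}

#' @rdname result_row
#' @param results A results tibble (rows from [result_row()]).
#' @param path Output file.
#' @export
write_results <- function(results, path) {
  stopifnot(identical(names(results), .result_columns()))
  out <- results
  num <- vapply(out, is.numeric, TRUE)
  out[num] <- lapply(out[num], signif, digits = 6)
  .write_tsv_atomic(out, path)
}

#' @rdname result_row
#' @export
read_results <- function(path) {
  res <- readr::read_tsv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           group1 = "c", group2 = "c", .default = "d"))
  stopifnot(identical(names(res), .result_columns()))
  res
}

#' Run configuration
#'
#' Flat `key = value` text configuration for the command-line interface.
#' Recognised keys and defaults: `step_cM` (2), `n_perm` (1000), `alpha`
#' (0.05), `em_tol` (1e-8), `em_max_iter` (2000), `seed` (none),
#' `min_class_mass` (1e-10).  Command-line flags override file values.
#'
#' @param path Optional path to a config file.
#' @return A named list of settings.
#' @export
read_run_config <- function(path = NULL) {
  cfg <- list(step_cM = 2, n_perm = 1000, alpha = 0.05, em_tol = 1e-8,
              em_max_iter = 2000, seed = NULL, min_class_mass = 1e-10)
  if (is.null(path)) return(cfg)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2)
      stop("bad config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1])
    if (!key %in% names(cfg))
      stop("unknown config key: '", key, "'", call. = FALSE)
    cfg[[key]] <- as.numeric(trimws(kv[2]))
  }
  cfg
}
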