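measurement_schema <- c("plant_id", "genotype", "organ_type", "step_index",
                        "raw_angle_deg", "step_direction", "internode_mm",
                        "node_position", "radius_mm")

#' Read and write measurement tables
#'
#' The canonical table dialect is TSV (tab-delimited, UTF-8, `#` comment
#' lines); CSV is accepted on input. One row per organ step with columns
#' `plant_id`, `genotype`, `organ_type`, `step_index`, `raw_angle_deg`,
#' `step_direction`, `internode_mm`, `node_position`, `radius_mm` (optional
#' extras `age_days`, `height_mm` are carried through).
#'
#' @param path File path.
#' @return `read_measurements`: a data frame; rows are checked against the
#'   schema and violations are reported with row numbers.
#' @export
read_measurements <- function(path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                          stringsAsFactors = FALSE)
  missing_cols <- setdiff(measurement_schema[1:6], names(df))
  if (length(missing_cols) > 0L) {
    stop("measurement table lacks columns: ",
         paste(missing_cols, collapse = ", "))
  }
  bad <- which(!is.finite(df$raw_angle_deg) | df$raw_angle_deg < 0 |
                 df$raw_angle_deg >= 360)
  if (length(bad) > 0L) {
    stop("raw_angle_deg outside [0, 360) at rows: ",
         paste(utils::head(bad, 10), collapse = ", "))
  }
  bad_dir <- which(!df$step_direction %in% c("CW", "CCW"))
  if (length(bad_dir) > 0L) {
    stop("invalid step_direction at rows: ",
         paste(utils::head(bad_dir, 10), collapse = ", "))
  }
  df
}

#' @rdname read_measurements
#' @param table Measurement-table data frame.
#' @param seed Optional generating seed recorded in a header comment.
#' @export
write_measurements <- function(table, path, seed = attr(table, "seed")) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(seed)) writeLines(sprintf("# seed: %s", seed), con)
  utils::write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Build inflorescence records from a measurement table
#'
#' Groups a measurement table by plant, assigns chirality from the per-step
#' rotation directions ([assign_chirality()]), drops plants without dominant
#' chirality (with a message), normalizes the raw world-frame angles into the
#' plant's own spiral frame ([normalize_divergence()]), and pairs angles with
#' internodes positionally.
#'
#' @param table Measurement-table data frame (see [read_measurements()]).
#' @param measurement_sense World rotation sense of `raw_angle_deg`.
#' @return Named list of [inflorescence_record()]s (ambiguous plants absent).
#' @export
measurements_to_records <- function(table, measurement_sense = "CW") {
  split_tab <- split(table, table$plant_id)
  records <- list()
  dropped <- character(0)
  for (plant in names(split_tab)) {
    d <- split_tab[[plant]]
    d <- d[order(d$step_index), ]
    chir <- assign_chirality(d$step_direction)
    if (chir == "ambiguous") {
      dropped <- c(dropped, plant)
      next
    }
    angles <- normalize_divergence(d$raw_angle_deg, chir,
                                   measurement_sense = measurement_sense)
    ser <- organ_series(plant_id = plant, angles = angles,
                        organ_type = d$organ_type[1], chirality = chir,
                        step_directions = d$step_direction,
                        genotype = d$genotype[1])
    records[[plant]] <- inflorescence_record(
      ser, d$internode_mm, node_positions = d$node_position,
      radii = if (all(is.na(d$radius_mm))) NULL else d$radius_mm)
  }
  if (length(dropped) > 0L) {
    message("dropped ", length(dropped),
            " plant(s) without dominant chirality: ",
            paste(dropped, collapse = ", "))
  }
  records
}

#' Write / read a 2D bin grid as TSV
#'
#' Serializes a [bin_pairs()] grid to a TSV matrix with a header row/column
#' of bin centers plus a `#`-commented sidecar metadata block (bin width,
#' number of pairs, golden-window edges).
#'
#' @param grid A `bin_grid2d`.
#' @param path Output path.
#' @export
write_bin_grid <- function(grid, path) {
  stopifnot(inherits(grid, "bin_grid2d"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# bin_width: %g", grid$bin_width),
               sprintf("# n_pairs: %d", grid$n_pairs),
               sprintf("# window_edges: %g %g", grid$window_edges[1],
                       grid$window_edges[2])), con)
  m <- cbind(center = grid$centers, grid$counts)
  utils::write.table(m, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_bin_grid
#' @export
read_bin_grid <- function(path) {
  hdr <- readLines(path, n = 10)
  meta <- hdr[startsWith(hdr, "#")]
  get <- function(key) {
    line <- meta[grepl(paste0("# ", key, ":"), meta, fixed = TRUE)]
    strsplit(sub(paste0("# ", key, ": "), "", line, fixed = TRUE), " ")[[1]]
  }
  bin_width <- as.numeric(get("bin_width"))
  m <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#",
                         check.names = FALSE)
  counts <- as.matrix(m[, -1, drop = FALSE])
  centers <- m$center
  dimnames(counts) <- list(centers, centers)
  structure(
    list(bin_width = bin_width, centers = centers,
         counts = counts, window_bins = golden_window_bins(bin_width),
         window_edges = as.numeric(get("window_edges")),
         n_pairs = as.integer(get("n_pairs"))),
    class = "bin_grid2d"
  )
}

#' Quantify phyllotactic regularity of a measurement table
#'
#' The quantify stage: chirality assignment, normalization, 2D binning of the
#' pooled consecutive angle pairs (pairs never straddle plants), and
#' per-plant golden-window fractions. Deterministic given its input. The
#' M-shaped motif filter is NOT applied here — it belongs to the
#' divergence-vs-internode analysis only.
#'
#' @param table Measurement-table data frame or path to one.
#' @param bin_width Bin width in degrees.
#' @param out_dir Optional directory; when given, writes `heatmap.tsv` and
#'   `window_fractions.tsv` there.
#' @return List with `grid` (a `bin_grid2d`), `window_fractions` (data frame
#'   plant_id/genotype/chirality/n_pairs/window_fraction) and `records`.
#' @export
run_quantify <- function(table, bin_width = 22.5, out_dir = NULL) {
  if (is.character(table)) table <- read_measurements(table)
  records <- measurements_to_records(table)
  if (length(records) == 0L) stop("no plants with dominant chirality")
  grids <- lapply(records, function(r) bin_pairs(r$series$angles, bin_width))
  counts <- Reduce(`+`, lapply(grids, `[[`, "counts"))
  grid <- grids[[1L]]
  grid$counts <- counts
  grid$n_pairs <- sum(vapply(grids, `[[`, integer(1), "n_pairs"))
  wf <- data.frame(
    plant_id = names(records),
    genotype = vapply(records, function(r) r$series$genotype, character(1)),
    chirality = vapply(records, function(r) r$series$chirality, character(1)),
    n_pairs = vapply(grids, `[[`, integer(1), "n_pairs"),
    window_fraction = vapply(records, function(r) {
      window_pair_fraction(r$series, bin_width)
    }, numeric(1)),
    row.names = NULL)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_bin_grid(grid, file.path(out_dir, "heatmap.tsv"))
    utils::write.table(wf, file.path(out_dir, "window_fractions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(grid = grid, window_fractions = wf, records = records)
}

#' Chirality-stratified divergence-vs-internode regressions for a table
#'
#' Builds records from a measurement table and fits
#' [divergence_vs_internode()] separately for clockwise and counterclockwise
#' plants, with the M-shaped motif filter on.
#'
#' @inheritParams run_quantify
#' @param internode_bin_width,min_per_bin Passed to
#'   [divergence_vs_internode()].
#' @return List with elements `CW` and `CCW` (each a `div_intern_fit`) and a
#'   tidy `summary` data frame (one row per chirality class).
#' @export
run_regress <- function(table, internode_bin_width = 0.1, min_per_bin = 4,
                        out_dir = NULL) {
  if (is.character(table)) table <- read_measurements(table)
  records <- measurements_to_records(table)
  fits <- lapply(c(CW = "CW", CCW = "CCW"), function(ch) {
    divergence_vs_internode(records, internode_bin_width, min_per_bin,
                            chirality = ch, apply_m_filter = TRUE)
  })
  summary <- do.call(rbind, lapply(names(fits), function(ch) {
    f <- fits[[ch]]
    data.frame(test_name = "divergence_vs_internode", groups = ch,
               statistic = f$slope, p_raw = f$p_value, p_bh = f$p_value,
               tail = "two", n = f$n_bins, pearson_r = f$pearson_r)
  }))
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(summary, file.path(out_dir, "regressions.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  c(fits, list(summary = summary))
}

#' Run the bulk-segregant candidate filter on a variant table
#'
#' Accepts a `bsa_pools` object ([generate_bsa_pools()]), a variant data
#' frame, or a VCF path plus pool sample names; subtracts parent variants
#' when supplied; writes the passing candidates and an exclusion-reasons
#' table when `out_dir` is given.
#'
#' @param variants A `bsa_pools`, data frame, or VCF path.
#' @param parent_variants Optional parent variant data frame
#'   (chrom/pos/ref/alt) or TSV path.
#' @param thresholds A [filter_thresholds()].
#' @param pheno_minus,pheno_plus VCF sample names (when `variants` is a VCF
#'   path).
#' @param out_dir Optional output directory.
#' @return List with `candidates` and `excluded` data frames.
#' @export
run_bsa <- function(variants, parent_variants = NULL,
                    thresholds = filter_thresholds(),
                    pheno_minus = "pheno_minus", pheno_plus = "pheno_plus",
                    out_dir = NULL) {
  if (inherits(variants, "bsa_pools")) {
    if (is.null(parent_variants)) parent_variants <- variants$parent_variants
    variants <- variants$variants
  } else if (is.character(variants)) {
    variants <- read_pool_vcf(variants, pheno_minus, pheno_plus)
  }
  if (is.character(parent_variants)) {
    parent_variants <- utils::read.table(parent_variants, header = TRUE,
                                         sep = "\t", comment.char = "#",
                                         stringsAsFactors = FALSE)
  }
  if (!is.null(parent_variants)) {
    variants <- subtract_parent_variants(variants, parent_variants)
  }
  all_annot <- filter_candidates(variants, thresholds, return_all = TRUE)
  candidates <- all_annot[all_annot$pass, ]
  excluded <- all_annot[!all_annot$pass, ]
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    utils::write.table(candidates, file.path(out_dir, "candidates.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(excluded[, c("chrom", "pos", "ref", "alt", "reason")],
                       file.path(out_dir, "excluded.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(candidates = candidates, excluded = excluded)
}

#' Read a two-pool variant table from a VCF
#'
#' Parses a VCF 4.x with per-sample AD fields for the two pool samples into
#' the [filter_candidates()] schema. Records with more than one ALT allele
#' are kept but flagged `biallelic = FALSE` (the default thresholds drop
#' them).
#'
#' @param path VCF path (plain text or bgzipped).
#' @param pheno_minus,pheno_plus Sample names of the two pools.
#' @return Variant data frame.
#' @export
read_pool_vcf <- function(path, pheno_minus = "pheno_minus",
                          pheno_plus = "pheno_plus") {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")
  if (!all(c(pheno_minus, pheno_plus) %in% colnames(ad))) {
    stop("VCF lacks pool samples: ", pheno_minus, ", ", pheno_plus)
  }
  split_ad <- function(x) {
    parts <- strsplit(ifelse(is.na(x), "0,0", x), ",")
    list(ref = as.integer(vapply(parts, `[`, character(1), 1)),
         alt = as.integer(vapply(parts, function(p) {
           if (length(p) >= 2) p[2] else "0"
         }, character(1))))
  }
  adm <- split_ad(ad[, pheno_minus])
  adp <- split_ad(ad[, pheno_plus])
  data.frame(
    chrom = fix[, "CHROM"], pos = as.integer(fix[, "POS"]),
    ref = fix[, "REF"], alt = fix[, "ALT"],
    biallelic = !grepl(",", fix[, "ALT"], fixed = TRUE),
    ad_ref_minus = adm$ref, ad_alt_minus = adm$alt,
    ad_ref_plus = adp$ref, ad_alt_plus = adp$alt,
    row.names = NULL)
}

#' Write a two-pool variant table as a plain-text VCF
#'
#' Emits a minimal VCF 4.2 with GT:AD fields for the two pool samples, so
#' synthetic pools round-trip through [read_pool_vcf()].
#'
#' @param variants Variant data frame ([filter_candidates()] schema).
#' @param path Output path.
#' @param pheno_minus,pheno_plus Sample names to write.
#' @param seed Optional generating seed recorded in the header.
#' @export
write_pool_vcf <- function(variants, path, pheno_minus = "pheno_minus",
                           pheno_plus = "pheno_plus", seed = NULL) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    if (!is.null(seed)) sprintf("##phyllotorsion_seed=%s", seed),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", pheno_minus, pheno_plus, sep = "\t"))
  body <- sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\t.\tGT:AD\t./.:%d,%d\t./.:%d,%d",
                  variants$chrom, variants$pos, variants$ref, variants$alt,
                  variants$ad_ref_minus, variants$ad_alt_minus,
                  variants$ad_ref_plus, variants$ad_alt_plus)
  writeLines(c(hdr, body), path)
  invisible(path)
}
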