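#' Read a two-group table from a delimited file
#'
#' Reads a CSV/TSV file (delimiter sniffed unless `sep` is given), validates
#' that the value column is numeric and the class column has exactly two
#' levels after dropping rows with missing values, and returns a
#' `labeled_sample`. Which observed label becomes group 1 (and hence the
#' sign of the effect size) defaults to sorted label order and can be
#' overridden with `group_order`.
#'
#' @param path Path to the delimited file.
#' @param value_col Name of the numeric column (default `"value"`).
#' @param class_col Name of the two-level class column (default `"group"`).
#' @param sep Field delimiter; `NULL` (default) lets the reader sniff it.
#' @param group_order Optional length-2 vector giving the label order
#'   (group 1, group 2).
#' @return A `labeled_sample` with attribute `group_labels` recording the
#'   original labels in (group 1, group 2) order.
#' @export
read_two_group_table <- function(path, value_col = "value",
                                 class_col = "group", sep = NULL,
                                 group_order = NULL) {
  if (!file.exists(path)) stop_input("input file not found: ", path)
  args <- list(input = path, data.table = FALSE, showProgress = FALSE)
  if (!is.null(sep)) args$sep <- sep
  d <- do.call(data.table::fread, args)
  for (col in c(value_col, class_col)) {
    if (!col %in% names(d)) {
      stop_input("column '", col, "' not found; available: ",
                 paste(names(d), collapse = ", "))
    }
  }
  raw_values <- d[[value_col]]
  if (!is.numeric(raw_values)) {
    bad <- which(is.na(suppressWarnings(as.numeric(raw_values))) &
                   !is.na(raw_values) & raw_values != "")
    if (length(bad) > 0) {
      stop_input("non-numeric value in column '", value_col, "' at row ",
                 bad[1])
    }
    raw_values <- suppressWarnings(as.numeric(raw_values))
  }
  cls <- d[[class_col]]
  keep <- !is.na(raw_values) & !is.na(cls) & cls != ""
  if (any(!keep)) {
    message(sum(!keep), " row(s) with missing values dropped")
  }
  values <- raw_values[keep]
  cls <- cls[keep]
  lev <- if (is.null(group_order)) sort(unique(cls)) else group_order
  if (length(unique(cls)) != 2L) {
    stop_input("class column '", class_col, "' must have exactly 2 levels, ",
               "found ", length(unique(cls)), ": ",
               paste(sort(unique(cls)), collapse = ", "))
  }
  if (!all(cls %in% lev)) {
    stop_input("labels outside 'group_order': ",
               paste(setdiff(unique(cls), lev), collapse = ", "))
  }
  out <- labeled_sample(values[cls == lev[1]], values[cls == lev[2]])
  attr(out, "group_labels") <- as.character(lev)
  out
}

# Serializable view of an impact_result plus both Cohen's d variants.
.result_payload <- function(res, x1, x2) {
  d_rms <- suppressWarnings(cohens_d(x1, x2, "rms"))
  d_nw <- suppressWarnings(cohens_d(x1, x2, "n_weighted"))
  list(
    impact = res$impact, ct_diff = res$ct_diff, morph_diff = res$morph_diff,
    gmd_pooled = res$gmd_pooled, ct_weight = res$ct_weight,
    dir_ct = res$dir_ct, dir_morph = res$dir_morph,
    gate_pvalue = res$gate_pvalue, gated_zero = res$gated_zero,
    n1 = res$n1, n2 = res$n2,
    group_levels = as.character(res$group_levels),
    cohens_d_rms = d_rms, cohens_d_n_weighted = d_nw,
    cohens_d_undefined = is.na(d_rms) || is.na(d_nw),
    config = unclass(res$config)
  )
}

#' Command-line entry point: compute the effect size for one file
#'
#' Parses `args` (see the package's `exec/impactsize` script), reads the
#' input table, computes the Impact effect size and both Cohen's d variants,
#' and writes a JSON report (stdout by default). All numeric fields are
#' serialized at full precision so the JSON round-trips exactly.
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code, invisibly (0 on success).
#' @export
cli_compute <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--value-col", type = "character",
                          default = "value", dest = "value_col"),
    optparse::make_option("--class-col", type = "character",
                          default = "group", dest = "class_col"),
    optparse::make_option("--alpha", type = "double", default = 0.05),
    optparse::make_option("--epsilon", type = "double", default = 1e-7),
    optparse::make_option("--density", type = "character", default = "pde"),
    optparse::make_option("--grid-points", type = "integer", default = 512L,
                          dest = "grid_points"),
    optparse::make_option("--absolute", action = "store_true",
                          default = FALSE),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--plot", type = "character", default = NULL,
                          help = "write a density plot PNG to this path"),
    optparse::make_option("--out", type = "character", default = "-",
                          help = "output JSON path ('-' for stdout)")
  )
  parser <- optparse::OptionParser(
    usage = "impactsize compute [options] <input.csv>", option_list = spec)
  status <- tryCatch({
    parsed <- optparse::parse_args(parser, args = args,
                                   positional_arguments = 1)
    opt <- parsed$options
    cfg <- impact_config(alpha = opt$alpha, epsilon = opt$epsilon,
                         density_method = opt$density,
                         grid_points = opt$grid_points, seed = opt$seed,
                         absolute_value = opt$absolute)
    s <- read_two_group_table(parsed$args[1], value_col = opt$value_col,
                              class_col = opt$class_col)
    res <- impact(s, config = cfg)
    g <- as_two_groups(s)
    if (!is.null(opt$plot)) {
      grDevices::png(opt$plot, width = 800, height = 500)
      plot_group_densities(s, config = cfg, main = basename(parsed$args[1]))
      grDevices::dev.off()
    }
    payload <- .result_payload(res, g$x1, g$x2)
    payload$input <- parsed$args[1]
    json <- jsonlite::toJSON(payload, auto_unbox = TRUE, digits = NA,
                             na = "null", null = "null", pretty = TRUE)
    if (identical(opt$out, "-")) cat(json, "\n") else writeLines(json, opt$out)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}

#' Command-line entry point: generate a synthetic benchmark suite
#'
#' Writes every subset of the requested benchmark suite (1-4) as a CSV file
#' (columns `value`, `group`) plus a `manifest.json` listing the files, the
#' seed and the generator. Suite 3 emits both scans (200 files).
#'
#' @param args Character vector of command-line arguments.
#' @return Integer exit code, invisibly (0 on success).
#' @export
cli_simulate <- function(args = commandArgs(trailingOnly = TRUE)) {
  spec <- list(
    optparse::make_option("--dataset", type = "integer", default = NA_integer_),
    optparse::make_option("--seed", type = "integer", default = 1L),
    optparse::make_option("--out-dir", type = "character", default = ".",
                          dest = "out_dir")
  )
  parser <- optparse::OptionParser(
    usage = "impactsize simulate --dataset <1-4> [options]",
    option_list = spec)
  status <- tryCatch({
    opt <- optparse::parse_args(parser, args = args)
    if (is.na(opt$dataset) || !opt$dataset %in% 1:4) {
      stop_input("--dataset must be one of 1, 2, 3, 4")
    }
    samples <- switch(opt$dataset,
      make_dataset1(seed = opt$seed),
      make_dataset2(seed = opt$seed),
      {
        v <- make_dataset3_variance_scan(seed = opt$seed)
        m <- make_dataset3_mean_scan(seed = opt$seed)
        names(v) <- sprintf("variance_scan_%03d", seq_along(v))
        names(m) <- sprintf("mean_scan_%03d", seq_along(m))
        c(v, m)
      },
      {
        d4 <- make_dataset4(seed = opt$seed)
        n1 <- sum(d4$group == 1)
        out <- lapply(d4$data, function(col) {
          labeled_sample(col[d4$group == 1], col[d4$group == 2])
        })
        names(out) <- names(d4$data)
        out
      }
    )
    paths <- write_labeled_samples(samples, opt$out_dir,
                                   prefix = sprintf("ds%d_", opt$dataset))
    manifest <- list(dataset = opt$dataset, seed = opt$seed,
                     n_subsets = length(samples), files = basename(paths))
    jsonlite::write_json(manifest, file.path(opt$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    0L
  }, error = function(e) {
    message("error: ", conditionMessage(e))
    1L
  })
  invisible(status)
}
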