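#' Indicator metadata table
#'
#' Constructs and validates the per-indicator metadata used throughout the
#' package: an identifier, a human-readable name, an orientation (whether
#' larger values are better), and units.
#'
#' @param indicator_id character vector of unique indicator identifiers.
#' @param name character vector of display names (defaults to the ids).
#' @param orientation character vector, each element `"positive"` (larger is
#'   better) or `"negative"` (smaller is better).
#' @param units character vector of unit strings (may be `""`).
#' @return A `data.frame` of class `indicator_meta`.
#' @export
indicator_meta <- function(indicator_id, name = indicator_id,
                           orientation = "positive", units = "") {
  indicator_id <- as.character(indicator_id)
  if (anyDuplicated(indicator_id))
    stop("indicator ids must be unique: ",
         paste(indicator_id[duplicated(indicator_id)], collapse = ", "))
  orientation <- rep_len(as.character(orientation), length(indicator_id))
  bad <- !orientation %in% c("positive", "negative")
  if (any(bad))
    stop("orientation must be 'positive' or 'negative' (got '",
         orientation[bad][1L], "' for ", indicator_id[bad][1L], ")")
  out <- data.frame(
    indicator_id = indicator_id,
    name = rep_len(as.character(name), length(indicator_id)),
    orientation = orientation,
    units = rep_len(as.character(units), length(indicator_id)),
    stringsAsFactors = FALSE
  )
  class(out) <- c("indicator_meta", "data.frame")
  out
}

#' Treatment design table
#'
#' Describes the factorial treatments: pyrolysis temperature (deg C, `NA` for
#' an untreated control) and biochar application rate (t/ha, 0 for the
#' control). A temperature must be present exactly when the rate is positive.
#'
#' @param treatment_id character vector of unique treatment labels.
#' @param temperature numeric pyrolysis temperatures (`NA` for control).
#' @param rate numeric application rates, `>= 0`.
#' @return A `data.frame` of class `treatment_design`.
#' @export
treatment_design <- function(treatment_id, temperature, rate) {
  treatment_id <- as.character(treatment_id)
  if (anyDuplicated(treatment_id))
    stop("treatment ids must be unique")
  temperature <- as.numeric(temperature)
  rate <- as.numeric(rate)
  if (any(rate < 0, na.rm = TRUE)) stop("application rate must be >= 0")
  mism <- xor(!is.na(temperature), rate > 0)
  if (any(mism))
    stop("pyrolysis temperature must be present exactly when rate > 0 ",
         "(offending treatment: ", treatment_id[mism][1L], ")")
  out <- data.frame(treatment_id = treatment_id, temperature = temperature,
                    rate = rate, stringsAsFactors = FALSE)
  class(out) <- c("treatment_design", "data.frame")
  out
}

#' Trial table: treatments by indicators for one year
#'
#' The central data container: a numeric matrix of indicator values with one
#' row per treatment and one column per indicator, together with indicator
#' metadata and (optionally) the treatment design. No missing cells are
#' accepted; the evaluation stages require a complete table.
#'
#' @param values numeric matrix, rownames = treatment ids, colnames =
#'   indicator ids.
#' @param meta an [indicator_meta()] covering every column.
#' @param design optional [treatment_design()] covering every row.
#' @param year label for the trial year (e.g. `"2023"` or `"2023-2024"`).
#' @return An object of class `trial_table`.
#' @export
trial_table <- function(values, meta, design = NULL, year = "") {
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("values must have treatment rownames and indicator colnames")
  if (anyNA(values) || any(!is.finite(values)))
    stop("trial table has missing or non-finite cells")
  if (!inherits(meta, "indicator_meta")) stop("meta must be an indicator_meta")
  unknown <- setdiff(colnames(values), meta$indicator_id)
  if (length(unknown))
    stop("columns without metadata: ", paste(unknown, collapse = ", "))
  meta <- meta[match(colnames(values), meta$indicator_id), , drop = FALSE]
  rownames(meta) <- NULL
  class(meta) <- c("indicator_meta", "data.frame")
  if (!is.null(design)) {
    if (!inherits(design, "treatment_design"))
      stop("design must be a treatment_design")
    missing_t <- setdiff(rownames(values), design$treatment_id)
    if (length(missing_t))
      stop("treatments without design rows: ",
           paste(missing_t, collapse = ", "))
    design <- design[match(rownames(values), design$treatment_id), ,
                     drop = FALSE]
    rownames(design) <- NULL
    class(design) <- c("treatment_design", "data.frame")
  }
  structure(list(values = values, meta = meta, design = design,
                 year = as.character(year)),
            class = "trial_table")
}

#' @export
print.trial_table <- function(x, ...) {
  cat("Trial table", if (nzchar(x$year)) paste0("(", x$year, ")"), "-",
      nrow(x$values), "treatments x", ncol(x$values), "indicators\n")
  print(round(x$values, 3))
  invisible(x)
}

#' @export
dim.trial_table <- function(x) dim(x$values)

#' Read a trial table from CSV
#'
#' Expects a header row whose first column is `treatment_id` and whose
#' remaining columns are indicator ids, one data row per treatment. Every
#' cell must parse as a finite number.
#'
#' @param path path to a UTF-8, comma-separated file.
#' @param meta an [indicator_meta()] covering every indicator column.
#' @param design optional [treatment_design()].
#' @param year year label (defaults to the file name stem).
#' @return A [trial_table()].
#' @export
read_trial_table <- function(path, meta, design = NULL,
                             year = sub("\\.[^.]*$", "", basename(path))) {
  raw <- tryCatch(
    utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE),
    error = function(e)
      stop("trial table file '", path, "' is empty or unreadable: ",
           conditionMessage(e), call. = FALSE))
  if (nrow(raw) == 0L || ncol(raw) < 2L)
    stop("trial table file '", path, "' is empty or has no indicator columns")
  ids <- as.character(raw[[1L]])
  if (anyDuplicated(ids))
    stop("duplicate treatment '", ids[duplicated(ids)][1L], "' in ", path)
  vals <- raw[, -1L, drop = FALSE]
  for (j in seq_along(vals)) {
    v <- suppressWarnings(as.numeric(vals[[j]]))
    if (anyNA(v))
      stop("non-numeric or missing cell in column '", names(vals)[j],
           "', row '", ids[which(is.na(v))[1L]], "' of ", path)
    vals[[j]] <- v
  }
  m <- as.matrix(vals)
  rownames(m) <- ids
  trial_table(m, meta = meta, design = design, year = year)
}

#' Write a trial table to CSV
#'
#' Inverse of [read_trial_table()]: the round trip through CSV preserves the
#' values to full double precision (15 significant digits are written).
#'
#' @param table a [trial_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_trial_table <- function(table, path) {
  stopifnot(inherits(table, "trial_table"))
  df <- data.frame(treatment_id = rownames(table$values),
                   table$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Average trial tables across years
#'
#' Cell-wise arithmetic mean of two or more structurally identical tables
#' (same treatments, same indicators, same order). The result carries a
#' combined year label such as `"2023-2024"`.
#'
#' @param tables a list of [trial_table()] objects (a single table is
#'   returned unchanged apart from its class invariants).
#' @return A [trial_table()] of the same shape.
#' @export
average_years <- function(tables) {
  if (inherits(tables, "trial_table")) tables <- list(tables)
  stopifnot(length(tables) >= 1L,
            all(vapply(tables, inherits, TRUE, "trial_table")))
  ref <- tables[[1L]]
  for (t in tables[-1L]) {
    if (!identical(dimnames(t$values), dimnames(ref$values)))
      stop("trial tables do not share the same treatments/indicators")
  }
  acc <- Reduce(`+`, lapply(tables, `[[`, "values"))
  yrs <- vapply(tables, `[[`, "", "year")
  trial_table(acc / length(tables), meta = ref$meta, design = ref$design,
              year = paste(yrs[nzchar(yrs)], collapse = "-"))
}

#' Built-in indicator metadata for the potato evaluation system
#'
#' The ten-indicator hierarchy used in the biochar trials: economic benefit
#' (yield Z11, net income Z12), tuber quality (starch Z21, vitamin C Z22,
#' reducing sugar Z23), water and fertilizer use efficiency (WUE Z31, PFP
#' Z32) and environmental benefit (soil nitrate Z41, available P Z42,
#' available K Z43 residues). Reducing sugar and the three soil residues are
#' negative-orientation (smaller is better) by default; residue orientation
#' is a judgement call and can be overridden with [indicator_meta()].
#'
#' @return An [indicator_meta()] with ten rows.
#' @export
potato_indicator_meta <- function() {
  indicator_meta(
    indicator_id = c("Z11", "Z12", "Z21", "Z22", "Z23",
                     "Z31", "Z32", "Z41", "Z42", "Z43"),
    name = c("tuber yield", "net income", "starch content",
             "vitamin C content", "reducing sugar content",
             "water use efficiency", "partial factor productivity",
             "soil nitrate residue", "soil available P residue",
             "soil available K residue"),
    orientation = c("positive", "positive", "positive", "positive",
                    "negative", "positive", "positive",
                    "negative", "negative", "negative"),
    units = c("t/ha", "CNY/ha", "%", "mg/100g", "%",
              "kg/m3", "kg/kg", "kg/ha", "kg/ha", "kg/ha")
  )
}

#' Built-in treatment design for the biochar factorial
#'
#' CK (no biochar) plus the 3 x 3 factorial of pyrolysis temperature
#' (300/500/700 deg C) and application rate (10/20/30 t/ha). Treatment labels
#' follow the rate-by-temperature convention (`C2T2` = 20 t/ha of 500 deg C
#' biochar).
#'
#' @return A [treatment_design()] with ten rows.
#' @export
potato_treatment_design <- function() {
  temps <- c(300, 500, 700)
  rates <- c(10, 20, 30)
  ids <- c("CK", as.vector(outer(seq_along(rates), seq_along(temps),
                                 function(c, t) paste0("C", c, "T", t))))
  treatment_design(
    treatment_id = ids,
    temperature = c(NA, rep(temps, each = 3)),
    rate = c(0, rep(rates, times = 3))
  )
}

# meta for the raw transcribed tables (columns beyond the Z system)
.raw_fixture_meta <- function() {
  indicator_meta(
    indicator_id = c("shoot_dm", "tuber_dm", "root_dm", "plant_height",
                     "stem_diameter", "lai", "spad", "yield",
                     "starch", "reducing_sugar", "vitamin_c",
                     "wue", "pfp",
                     "water_fee", "fertilizer_input", "other_input",
                     "gross_income", "net_income"),
    orientation = c(rep("positive", 9), "negative", "positive",
                    "positive", "positive",
                    "negative", "negative", "negative",
                    "positive", "positive"),
    units = c("t/ha", "t/ha", "t/ha", "cm", "mm", "m2/m2", "", "t/ha",
              "%", "%", "mg/100g", "kg/m3", "kg/kg",
              rep("CNY/ha", 5))
  )
}

#' Load a packaged example trial table
#'
#' Reads one of the transcribed example tables shipped with the package:
#' `"growth"`, `"quality"`, `"efficiency"` or `"economics"`, for 2023 or
#' 2024.
#'
#' @param which table name.
#' @param year 2023 or 2024.
#' @return A [trial_table()] with the raw column names of the source table.
#' @export
example_trial_table <- function(which = c("growth", "quality", "efficiency",
                                          "economics"),
                                year = 2023) {
  which <- match.arg(which)
  path <- system.file("extdata", paste0(which, "_", year, ".csv"),
                      package = "pfce", mustWork = TRUE)
  read_trial_table(path, meta = .raw_fixture_meta(),
                   design = potato_treatment_design(), year = as.character(year))
}

#' Assemble the seven-indicator evaluation table for one year
#'
#' Combines the packaged growth, economics, quality and efficiency tables
#' into a single trial table over the seven indicators with published
#' numeric values: Z11 (yield), Z12 (net income), Z21 (starch), Z22
#' (vitamin C), Z23 (reducing sugar), Z31 (WUE) and Z32 (PFP). The three
#' soil-residue indicators (Z41-Z43) have no published table and are
#' omitted; evaluation functions renormalize weights over the indicators
#' present.
#'
#' @param year 2023 or 2024.
#' @return A [trial_table()] with seven columns.
#' @export
potato_evaluation_table <- function(year = 2023) {
  g <- example_trial_table("growth", year)
  e <- example_trial_table("economics", year)
  q <- example_trial_table("quality", year)
  f <- example_trial_table("efficiency", year)
  vals <- cbind(
    Z11 = g$values[, "yield"],
    Z12 = e$values[, "net_income"],
    Z21 = q$values[, "starch"],
    Z22 = q$values[, "vitamin_c"],
    Z23 = q$values[, "reducing_sugar"],
    Z31 = f$values[, "wue"],
    Z32 = f$values[, "pfp"]
  )
  trial_table(vals, meta = potato_indicator_meta(),
              design = potato_treatment_design(), year = as.character(year))
}
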