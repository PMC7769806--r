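#' Canonical panel columns
#'
#' Default input and output quantity names for a health-resource panel.
#' @keywords internal
#' @noRd
default_inputs <- function() c("institutions", "beds", "staff")

#' @noRd
default_outputs <- function() c("outpatient_visits", "discharged_patients")

#' Construct a validated resource panel
#'
#' A resource panel is a long (tidy) table with one row per decision-making
#' unit (DMU, e.g. a province) and year, carrying input quantities, output
#' quantities, the population and land area used as allocation bases, and a
#' region-group label. It is the single container that all equity, DEA and
#' Malmquist stages read.
#'
#' @param data A data frame with columns `dmu`, `year`, `group`, one column
#'   per input and output quantity, `population`, and `area_km2`.
#' @param inputs Character vector naming the input-quantity columns.
#' @param outputs Character vector naming the output-quantity columns.
#'
#' @return A tibble of class `resource_panel` with `inputs`/`outputs`
#'   attributes recording which columns play which role.
#'
#' @details Validation enforces: every `(dmu, year)` pair appears at most
#'   once; every DMU carries exactly one group label across all years;
#'   population and area are finite and strictly positive; input and output
#'   quantities are finite and nonnegative. (DEA additionally requires strict
#'   positivity; see [panel_technology()].)
#'
#' @examples
#' pan <- gen_panel(panel_spec(seed = 1))
#' pan
#' @export
resource_panel <- function(data,
                           inputs = default_inputs(),
                           outputs = default_outputs()) {
  data <- tibble::as_tibble(data)
  required <- c("dmu", "year", "group", inputs, outputs, "population", "area_km2")
  missing <- setdiff(required, names(data))
  if (length(missing) > 0) {
    stop("panel is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  data$dmu <- as.character(data$dmu)
  data$group <- as.character(data$group)
  # numeric year labels are held as double so CSV round trips are exact
  if (is.numeric(data$year)) data$year <- as.numeric(data$year)

  dup <- duplicated(data[c("dmu", "year")])
  if (any(dup)) {
    offenders <- unique(paste0("(", data$dmu[dup], ", ", data$year[dup], ")"))
    stop("duplicate (dmu, year) pair(s): ", paste(offenders, collapse = ", "),
         call. = FALSE)
  }

  grp_n <- tapply(data$group, data$dmu, function(g) length(unique(g)))
  if (any(grp_n > 1)) {
    stop("DMU(s) with more than one group label: ",
         paste(names(grp_n)[grp_n > 1], collapse = ", "), call. = FALSE)
  }

  num_cols <- c(inputs, outputs, "population", "area_km2")
  for (col in num_cols) {
    v <- data[[col]]
    if (!is.numeric(v) || any(!is.finite(v))) {
      stop("column '", col, "' must be finite numeric", call. = FALSE)
    }
  }
  bad_base <- data$population <= 0 | data$area_km2 <= 0
  if (any(bad_base)) {
    offenders <- paste0("(", data$dmu[bad_base], ", ", data$year[bad_base], ")")
    stop("nonpositive population/area for: ",
         paste(offenders, collapse = ", "), call. = FALSE)
  }
  for (col in c(inputs, outputs)) {
    if (any(data[[col]] < 0)) {
      stop("negative values in quantity column '", col, "'", call. = FALSE)
    }
  }

  structure(data,
            inputs = inputs,
            outputs = outputs,
            class = c("resource_panel", class(tibble::tibble())))
}

#' @export
print.resource_panel <- function(x, ...) {
  cat("<resource_panel> ", length(unique(x$dmu)), " DMUs x ",
      length(unique(x$year)), " years; inputs: ",
      paste(attr(x, "inputs"), collapse = ", "), "; outputs: ",
      paste(attr(x, "outputs"), collapse = ", "), "\n", sep = "")
  NextMethod()
}

#' Input/output quantity names of a panel
#' @param panel A [resource_panel()].
#' @return Character vector of column names.
#' @export
panel_inputs <- function(panel) attr(panel, "inputs")

#' @rdname panel_inputs
#' @export
panel_outputs <- function(panel) attr(panel, "outputs")

#' Read a resource panel from CSV
#'
#' Reads a long-format CSV (one row per DMU and year) and validates it into a
#' [resource_panel()]. Column names in the file can differ from the canonical
#' ones; supply `schema` to map them.
#'
#' @param path Path to a UTF-8 CSV file with a header row.
#' @param schema Optional column-name mapping: a named character vector
#'   `c(canonical = "file_column", ...)`, or the path to a YAML file holding
#'   such a mapping. Canonical names: `dmu`, `year`, `group`, the input and
#'   output quantities, `population`, `area_km2`.
#' @inheritParams resource_panel
#'
#' @return A validated [resource_panel()]. Row order in the file does not
#'   affect any downstream result.
#' @export
read_panel <- function(path,
                       schema = NULL,
                       inputs = default_inputs(),
                       outputs = default_outputs()) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  if (!is.null(schema)) {
    if (is.character(schema) && is.null(names(schema)) && length(schema) == 1) {
      schema <- unlist(yaml::read_yaml(schema))
    }
    missing <- setdiff(unname(schema), names(df))
    if (length(missing) > 0) {
      stop("schema maps to column(s) absent from file: ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    for (canon in names(schema)) {
      names(df)[names(df) == schema[[canon]]] <- canon
    }
  }
  resource_panel(df, inputs = inputs, outputs = outputs)
}

#' Write a resource panel to CSV
#'
#' Writes the panel as a long-format CSV at full numeric precision, so that
#' [read_panel()] on the result reproduces the panel exactly.
#'
#' @param panel A [resource_panel()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_panel <- function(panel, path) {
  stopifnot(inherits(panel, "resource_panel"))
  readr::write_csv(tibble::as_tibble(unclass(panel)), path, progress = FALSE)
  invisible(path)
}

#' Per-capita and per-area resource densities
#'
#' Aggregates each resource over DMUs within each year and expresses the
#' total per 1,000 persons and per 1,000 square kilometres, the two
#' allocation bases used throughout the equity analysis.
#'
#' @param panel A [resource_panel()].
#' @param resources Which quantity columns to tabulate; defaults to the
#'   panel's inputs.
#'
#' @return A tibble with columns `year`, `resource`, `total`,
#'   `per_1000_persons`, `per_1000_km2`.
#' @export
density_table <- function(panel, resources = panel_inputs(panel)) {
  stopifnot(inherits(panel, "resource_panel"))
  df <- tibble::as_tibble(unclass(panel))
  long <- tidyr::pivot_longer(df[c("dmu", "year", "population", "area_km2", resources)],
                              cols = dplyr::all_of(resources),
                              names_to = "resource", values_to = "value")
  out <- dplyr::summarise(
    dplyr::group_by(long, .data$year, .data$resource),
    total = sum(.data$value),
    per_1000_persons = sum(.data$value) / (sum(.data$population) / 1000),
    per_1000_km2 = sum(.data$value) / (sum(.data$area_km2) / 1000),
    .groups = "drop"
  )
  out$resource <- factor(out$resource, levels = resources)
  dplyr::arrange(out, .data$year, .data$resource)
}

#' Mainland-China region grouping of the 31 province-level divisions
#'
#' The conventional three-way geographic split used in regional equity
#' studies: an eastern region of 8 provinces and 3 municipalities, a middle
#' region of 8 provinces, and a western region of 6 provinces, 5 autonomous
#' regions and 1 municipality (11 / 8 / 12 units).
#'
#' @return A named character vector mapping province name to
#'   `"eastern"`, `"middle"` or `"western"`.
#' @export
china_region_groups <- function() {
  c(Beijing = "eastern", Tianjin = "eastern", Hebei = "eastern",
    Liaoning = "eastern", Shanghai = "eastern", Jiangsu = "eastern",
    Zhejiang = "eastern", Fujian = "eastern", Shandong = "eastern",
    Guangdong = "eastern", Hainan = "eastern",
    Shanxi = "middle", Jilin = "middle", Heilongjiang = "middle",
    Anhui = "middle", Jiangxi = "middle", Henan = "middle",
    Hubei = "middle", Hunan = "middle",
    `Inner Mongolia` = "western", Guangxi = "western", Chongqing = "western",
    Sichuan = "western", Guizhou = "western", Yunnan = "western",
    Tibet = "western", Shaanxi = "western", Gansu = "western",
    Qinghai = "western", Ningxia = "western", Xinjiang = "western")
}
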