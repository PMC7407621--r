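#' Parse "value +/- error" cells
#'
#' @param x character vector of cells such as \code{"5.44 ± 0.77"},
#'   \code{"3.2"}, or empty.
#' @param what cell label used in error messages.
#' @return data.frame with \code{value} and \code{err} (NA where absent).
#' @keywords internal
parse_pm <- function(x, what = "cell") {
  x <- trimws(as.character(x))
  value <- err <- rep(NA_real_, length(x))
  for (i in seq_along(x)) {
    if (is.na(x[i]) || x[i] == "" || toupper(x[i]) == "ND") next
    parts <- strsplit(x[i], "±|\\+/-")[[1]]
    v <- suppressWarnings(as.numeric(trimws(parts[1])))
    if (is.na(v))
      stop("input error: unparseable numeric in ", what, " '", x[i], "'")
    value[i] <- v
    if (length(parts) > 1) {
      e <- suppressWarnings(as.numeric(trimws(parts[2])))
      if (is.na(e))
        stop("input error: unparseable error term in ", what, " '", x[i], "'")
      err[i] <- e
    }
  }
  data.frame(value = value, err = err)
}

#' Parse mutation tokens such as "L260F"
#'
#' @param tokens character vector; multiple mutations per record may be
#'   separated by \code{"/"}, \code{"+"} or whitespace.
#' @return list of data.frames with \code{wt, position, new}.
#' @export
parse_mutations <- function(tokens) {
  lapply(tokens, function(tk) {
    if (is.na(tk) || tk == "")
      return(data.frame(wt = character(0), position = integer(0),
                        new = character(0)))
    parts <- unlist(strsplit(tk, "[/+,[:space:]]+"))
    parts <- parts[parts != ""]
    ok <- grepl("^[A-Z][0-9]+[A-Z]$", parts)
    if (!all(ok))
      stop("input error: malformed mutation token '", parts[!ok][1], "'")
    data.frame(wt = substr(parts, 1, 1),
               position = as.integer(gsub("[A-Z]", "", parts)),
               new = substring(parts, nchar(parts)),
               stringsAsFactors = FALSE)
  })
}

field_aliases <- list(
  name = c("name", "variant", "clone"),
  mutations = c("mutations", "mutation"),
  kcat = c("kcat", "kcat_1_s", "kcat_s"),
  KM = c("km", "km_mm", "k_m"),
  efficiency = c("efficiency", "kcat_km", "kcat_over_km", "kcat_km_m_s"),
  TM = c("tm", "tm_c", "t_m"),
  dG_act_exp = c("dg_act_exp", "dg_exp", "dgexp"),
  dG_act_calc = c("dg_act_calc", "dg_calc", "dgcalc"),
  DA_distance = c("da_distance", "d_a_distance", "da_dist"),
  DHA_angle = c("dha_angle", "d_h_a_angle")
)

#' Load a delimited variant table
#'
#' Reads a tab- or comma-delimited table of enzyme variants (the shape of
#' the screening tables: name, mutations, kcat, KM, kcat/KM, TM,
#' experimental/calculated barriers, geometry). Header names are matched
#' through documented aliases; cells may carry "value ± error"; missing
#' cells become NA. Units are kcat in 1/s, KM in mM, efficiency in 1/M/s,
#' TM in degrees C, barriers in kcal/mol.
#'
#' @param delimited_text path to a file, or the table text itself.
#' @param sep field separator; default \code{"\t"}, with \code{","}
#'   autodetected.
#' @return a \code{variant_table} data.frame with columns \code{name,
#'   mutations, kcat, kcat_err, KM, KM_err, efficiency, efficiency_err, TM,
#'   dG_act_exp, dG_act_calc, dG_act_calc_sem, DA_distance, DHA_angle}.
#' @export
load_variant_table <- function(delimited_text, sep = NULL) {
  txt <- if (length(delimited_text) == 1 && !grepl("\n", delimited_text) &&
             file.exists(delimited_text)) readLines(delimited_text)
         else unlist(strsplit(delimited_text, "\n", fixed = TRUE))
  txt <- txt[!grepl("^\\s*(#|$)", txt)]
  if (!length(txt)) return(empty_variant_table())
  if (is.null(sep)) sep <- if (grepl("\t", txt[1])) "\t" else ","
  df <- read.delim(text = paste(txt, collapse = "\n"), sep = sep,
                   stringsAsFactors = FALSE, check.names = FALSE,
                   strip.white = TRUE)
  hdr <- tolower(gsub("[^a-z0-9_]+", "_", tolower(names(df))))
  col_for <- function(field) {
    m <- which(hdr %in% field_aliases[[field]])
    if (length(m)) df[[m[1]]] else NULL
  }
  nm <- col_for("name")
  if (is.null(nm)) stop("input error: no recognizable name/variant column")
  nm <- trimws(as.character(nm))
  if (anyDuplicated(nm))
    stop("input error: duplicate variant name '", nm[duplicated(nm)][1], "'")
  n <- length(nm)
  num <- function(field) {
    v <- col_for(field)
    if (is.null(v)) return(data.frame(value = rep(NA_real_, n),
                                      err = rep(NA_real_, n)))
    parse_pm(v, what = paste0(field, " cell"))
  }
  kcat <- num("kcat"); KM <- num("KM"); eff <- num("efficiency")
  TM <- num("TM"); dge <- num("dG_act_exp"); dgc <- num("dG_act_calc")
  dad <- num("DA_distance"); dha <- num("DHA_angle")
  muts <- col_for("mutations")
  muts <- if (is.null(muts)) rep(NA_character_, n) else as.character(muts)
  parse_mutations(muts)  # validates tokens
  out <- data.frame(name = nm, mutations = muts,
                    kcat = kcat$value, kcat_err = kcat$err,
                    KM = KM$value, KM_err = KM$err,
                    efficiency = eff$value, efficiency_err = eff$err,
                    TM = TM$value,
                    dG_act_exp = dge$value,
                    dG_act_calc = dgc$value, dG_act_calc_sem = dgc$err,
                    DA_distance = dad$value, DHA_angle = dha$value,
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}

empty_variant_table <- function() {
  out <- data.frame(name = character(0), mutations = character(0),
                    kcat = numeric(0), kcat_err = numeric(0),
                    KM = numeric(0), KM_err = numeric(0),
                    efficiency = numeric(0), efficiency_err = numeric(0),
                    TM = numeric(0), dG_act_exp = numeric(0),
                    dG_act_calc = numeric(0), dG_act_calc_sem = numeric(0),
                    DA_distance = numeric(0), DHA_angle = numeric(0),
                    stringsAsFactors = FALSE)
  class(out) <- c("variant_table", "data.frame")
  out
}

#' Packaged screening-table fixtures
#'
#' Returns one of the delimited variant tables shipped with the package:
#' \code{"table1"} (random-library clones: efficiency and TM),
#' \code{"table2"} (calibration single mutants: kcat, KM, efficiency,
#' experimental and calculated barriers), \code{"table3"} (the 20
#' stability-designed variants plus background: kcat, KM, efficiency, TM).
#'
#' @param which fixture name.
#' @return a \code{variant_table}.
#' @export
variant_table_fixture <- function(which = c("table2", "table3", "table1")) {
  which <- match.arg(which)
  load_variant_table(system.file("extdata", paste0(which, ".tsv"),
                                 package = "evbscreen", mustWork = TRUE))
}

#' Recompute catalytic efficiency from kcat and KM
#'
#' \code{kcat / KM} with KM converted from mM to M, compared with the
#' independently fitted efficiency column where present. Rows whose printed
#' efficiency deviates from kcat/KM by more than \code{flag_threshold}
#' (relative) are flagged as independently fitted / inconsistent.
#'
#' @param table a \code{variant_table} (or single-row record).
#' @param flag_threshold relative deviation flag level (default 0.05).
#' @return data.frame with \code{name, efficiency_recomputed,
#'   efficiency_printed, rel_deviation, inconsistent}.
#' @export
recompute_efficiency <- function(table, flag_threshold = 0.05) {
  if (any(!is.na(table$KM) & table$KM <= 0))
    stop("KM must be positive to recompute efficiency")
  rec <- table$kcat / (table$KM * 1e-3)
  rel <- abs(rec - table$efficiency) / table$efficiency
  data.frame(name = table$name, efficiency_recomputed = rec,
             efficiency_printed = table$efficiency, rel_deviation = rel,
             inconsistent = !is.na(rel) & rel > flag_threshold,
             stringsAsFactors = FALSE)
}

#' Fold range (max/min) of a positive field
#'
#' @param table a \code{variant_table}.
#' @param field column name, e.g. \code{"efficiency"}.
#' @return max/min ratio over the non-missing values.
#' @export
fold_range <- function(table, field = "efficiency") {
  v <- table[[field]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("no values present in field '", field, "'")
  if (any(v <= 0)) stop("fold range requires positive values")
  max(v) / min(v)
}

#' Count variants enhanced over a reference
#'
#' Counts non-reference records whose field is at least
#' \code{fold_threshold} times the reference value.
#'
#' @param table a \code{variant_table}.
#' @param reference_name name of the reference record.
#' @param field column to compare (default \code{"efficiency"}).
#' @param fold_threshold enhancement criterion (default 1.5).
#' @return list with \code{count} and \code{members} (names, table order).
#' @export
count_enhanced <- function(table, reference_name, field = "efficiency",
                           fold_threshold = 1.5) {
  stopifnot(fold_threshold > 0)
  iref <- match(reference_name, table$name)
  if (is.na(iref)) stop("input error: reference '", reference_name,
                        "' not in table")
  ref <- table[[field]][iref]
  sel <- which(table$name != reference_name &
                 !is.na(table[[field]]) &
                 table[[field]] >= fold_threshold * ref)
  list(count = length(sel), members = table$name[sel])
}

#' Range of experimental activation free energies over a subset
#'
#' Uses the experimental barrier column where present; otherwise derives it
#' from kcat via \code{\link{activation_free_energy}} and rounds to 1
#' decimal place (half away from zero), matching the convention of printed
#' tables.
#'
#' @param table a \code{variant_table}.
#' @param subset_names variant names to include.
#' @param T temperature for the Eyring conversion (K).
#' @return named vector \code{c(min =, max =)} in kcal/mol.
#' @export
barrier_range <- function(table, subset_names,
                          T = physical_constants$T_default) {
  if (!length(subset_names)) stop("input error: empty subset")
  idx <- match(subset_names, table$name)
  if (anyNA(idx)) stop("input error: unknown variant '",
                       subset_names[is.na(idx)][1], "'")
  dg <- table$dG_act_exp[idx]
  need <- is.na(dg)
  if (any(need)) {
    kc <- table$kcat[idx][need]
    if (anyNA(kc)) stop("barriers neither present nor derivable from kcat")
    dg[need] <- round_half_away(activation_free_energy(kc, T), 1)
  }
  c(min = min(dg), max = max(dg))
}

#' Round half away from zero
#'
#' Printed-table rounding convention (R's \code{round} rounds half to even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded numeric.
#' @export
round_half_away <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Pearson correlation between two variant-table fields
#'
#' Signed Pearson r with the least-squares line; rows missing either field
#' are dropped and counted.
#'
#' @param table a \code{variant_table} or data.frame.
#' @param x_field,y_field column names.
#' @return object of class \code{correlation_result}: \code{r, r_squared,
#'   slope, intercept, n, n_dropped}.
#' @export
correlate <- function(table, x_field, y_field) {
  x <- table[[x_field]]; y <- table[[y_field]]
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x) == 0 || stats::var(y) == 0)
    stop("undefined correlation: zero variance in '",
         if (stats::var(x) == 0) x_field else y_field, "'")
  r <- cor(x, y)
  fit <- lm(y ~ x)
  structure(list(r = r, r_squared = r^2,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1]),
                 n = length(x), n_dropped = sum(!keep)),
            class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  cat(sprintf("r = %.3f (r^2 = %.3f), y = %.3g x + %.3g, n = %d\n",
              x$r, x$r_squared, x$slope, x$intercept, x$n))
  invisible(x)
}

#' Screening summary report
#'
#' Ranks a variant table by a field and reports the headline screening
#' analytics: fold range, enhancement count over a reference, and (when
#' geometry columns are present) geometry-barrier correlations.
#'
#' @param table a \code{variant_table}.
#' @param reference_name reference variant for enhancement counting.
#' @param field ranking field (default \code{"efficiency"}).
#' @param fold_threshold enhancement criterion.
#' @return list with \code{ranking}, \code{fold_range}, \code{enhanced},
#'   and \code{correlations} (possibly empty).
#' @export
screen_report <- function(table, reference_name, field = "efficiency",
                          fold_threshold = 1.5) {
  ord <- order(-table[[field]], table$name)
  cors <- list()
  for (geo in c("DA_distance", "DHA_angle")) {
    for (dg in c("dG_act_calc", "dG_act_exp")) {
      if (sum(!is.na(table[[geo]]) & !is.na(table[[dg]])) >= 3)
        cors[[paste(dg, "vs", geo)]] <- correlate(table, geo, dg)
    }
  }
  list(ranking = table$name[ord],
       fold_range = fold_range(table, field),
       enhanced = count_enhanced(table, reference_name, field, fold_threshold),
       correlations = cors)
}
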