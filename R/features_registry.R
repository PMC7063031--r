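# The handcrafted feature registry: 56 methods producing 79 scalar
# outputs, organised in five functional groups --
#   SAP (signal amplitude and power, 25 methods),
#   FI  (frequency information, 5),
#   NLC (non-linear complexity, 6),
#   TSM (time-series modelling, 7),
#   UNI (unique, 13).
# Multi-output methods: AR / CC / DAR / DCC (order 4 -> 4 outputs each),
# HIST (3 bins), MHW / MTW (3 sub-windows each), TSPSD (6 descriptors).

.spec <- function(name, group, fn, n_outputs = 1, params = list()) {
  list(name = name, group = group, fn = fn, n_outputs = n_outputs,
       params = params)
}

#' Build the handcrafted feature registry
#'
#' @param fs sampling rate in Hz, stored into every spectral feature's
#'   parameters.
#' @param zc_threshold,ssc_threshold amplitude thresholds of the zero
#'   crossing and slope sign change counters (amplitude units).
#' @param wamp_threshold Willison amplitude threshold (amplitude units).
#' @param ar_order model order of the autoregressive / cepstral features.
#' @return object of class `feature_registry`: a list of feature specs
#'   (name, group, n_outputs, params) plus derived bookkeeping.
#' @export
feature_registry <- function(fs = 1000, zc_threshold = 0, ssc_threshold = 0,
                             wamp_threshold = 50, ar_order = 4) {
  sp <- list(
    ## SAP -------------------------------------------------------------
    .spec("AFB",   "SAP", fe_afb),
    .spec("DAMV",  "SAP", fe_damv),
    .spec("DASDV", "SAP", fe_dasdv),
    .spec("DLD",   "SAP", fe_dld),
    .spec("DTM",   "SAP", fe_dtm),
    .spec("DVARV", "SAP", fe_dvarv),
    .spec("DV",    "SAP", fe_dv, params = list(v = 2)),
    .spec("IEMG",  "SAP", fe_iemg),
    .spec("LD",    "SAP", fe_ld),
    .spec("M2",    "SAP", fe_m2),
    .spec("MMAV1", "SAP", fe_mmav1),
    .spec("MMAV2", "SAP", fe_mmav2),
    .spec("MAV",   "SAP", fe_mav),
    .spec("MAX",   "SAP", fe_max),
    .spec("MHW",   "SAP", fe_mhw, n_outputs = 3),
    .spec("MNP",   "SAP", fe_mnp, params = list(fs = fs)),
    .spec("MTW",   "SAP", fe_mtw, n_outputs = 3),
    .spec("RMS",   "SAP", fe_rms),
    .spec("SM",    "SAP", fe_sm, params = list(fs = fs)),
    .spec("SSI",   "SAP", fe_ssi),
    .spec("TM",    "SAP", fe_tm),
    .spec("TTP",   "SAP", fe_ttp, params = list(fs = fs)),
    .spec("VAR",   "SAP", fe_var),
    .spec("V",     "SAP", fe_v, params = list(v = 2)),
    .spec("WL",    "SAP", fe_wl),
    ## FI --------------------------------------------------------------
    .spec("FR",  "FI", fe_fr,
          params = list(fs = fs, low_band = c(20, 250), high_band = c(250, 500))),
    .spec("MDF", "FI", fe_mdf, params = list(fs = fs)),
    .spec("MNF", "FI", fe_mnf, params = list(fs = fs)),
    .spec("SSC", "FI", fe_ssc, params = list(threshold = ssc_threshold)),
    .spec("ZC",  "FI", fe_zc, params = list(threshold = zc_threshold)),
    ## NLC -------------------------------------------------------------
    .spec("SAMPEN", "NLC", fe_sampen, params = list(m = 2, r_frac = 0.2)),
    .spec("APEN",   "NLC", fe_apen, params = list(m = 2, r_frac = 0.2)),
    .spec("WAMP",   "NLC", fe_wamp, params = list(threshold = wamp_threshold)),
    .spec("BC",     "NLC", fe_bc),
    .spec("KATZ",   "NLC", fe_katz),
    .spec("MFL",    "NLC", fe_mfl),
    ## TSM -------------------------------------------------------------
    .spec("AR",  "TSM", fe_ar, n_outputs = ar_order, params = list(order = ar_order)),
    .spec("CC",  "TSM", fe_cc, n_outputs = ar_order, params = list(order = ar_order)),
    .spec("DAR", "TSM", fe_dar, n_outputs = ar_order, params = list(order = ar_order)),
    .spec("DCC", "TSM", fe_dcc, n_outputs = ar_order, params = list(order = ar_order)),
    .spec("DFA", "TSM", fe_dfa),
    .spec("PSR", "TSM", fe_psr, params = list(fs = fs, width = 10)),
    .spec("SNR", "TSM", fe_snr, params = list(fs = fs)),
    ## UNI -------------------------------------------------------------
    .spec("CE",    "UNI", fe_ce),
    .spec("DPR",   "UNI", fe_dpr, params = list(fs = fs)),
    .spec("HIST",  "UNI", fe_hist, n_outputs = 3, params = list(bins = 3)),
    .spec("KURT",  "UNI", fe_kurt),
    .spec("MAVS",  "UNI", fe_mavs),
    .spec("OHM",   "UNI", fe_ohm, params = list(fs = fs)),
    .spec("PKF",   "UNI", fe_pkf, params = list(fs = fs)),
    .spec("PSDFD", "UNI", fe_psdfd, params = list(fs = fs)),
    .spec("SKEW",  "UNI", fe_skew),
    .spec("SMR",   "UNI", fe_smr, params = list(fs = fs)),
    .spec("TSPSD", "UNI", fe_tspsd, n_outputs = 6),
    .spec("VCF",   "UNI", fe_vcf, params = list(fs = fs)),
    .spec("VFD",   "UNI", fe_vfd))
  names(sp) <- vapply(sp, `[[`, character(1), "name")
  .assert(!anyDuplicated(names(sp)), "feature names must be unique")
  out_names <- unlist(lapply(sp, function(s) {
    if (s$n_outputs == 1) s$name else paste0(s$name, seq_len(s$n_outputs))
  }), use.names = FALSE)
  out_groups <- unlist(lapply(sp, function(s) rep(s$group, s$n_outputs)),
                       use.names = FALSE)
  structure(list(entries = sp, output_names = out_names,
                 output_groups = out_groups),
            class = "feature_registry")
}

#' @export
print.feature_registry <- function(x, ...) {
  cat(sprintf("<feature_registry> %d methods, %d scalar outputs\n",
              length(x$entries), length(x$output_names)))
  print(table(vapply(x$entries, `[[`, character(1), "group")))
  invisible(x)
}

#' Number of methods / scalar outputs / per-group method counts
#' @param registry a [feature_registry()].
#' @export
registry_summary <- function(registry) {
  groups <- vapply(registry$entries, `[[`, character(1), "group")
  list(n_methods = length(registry$entries),
       n_outputs = length(registry$output_names),
       group_counts = table(factor(groups, levels = c("SAP", "FI", "NLC", "TSM", "UNI"))))
}

#' Compute one feature method on a single-channel window
#'
#' @param spec one entry of a [feature_registry()].
#' @param x numeric vector (one channel of one window).
#' @return numeric vector of length `spec$n_outputs`.
#' @export
compute_feature <- function(spec, x) {
  .assert(all(is.finite(x)), "input error: non-finite samples")
  v <- spec$fn(x, spec$params)
  .assert(length(v) == spec$n_outputs, sprintf("%s: wrong output length", spec$name))
  as.numeric(v)
}

#' Compute the full feature bank over a dataset
#'
#' @param dataset an `emg_dataset`.
#' @param registry a [feature_registry()].
#' @return a `feature_table`: `values` is an array
#'   `n_windows x n_channels x n_features` with named feature slices, plus
#'   the dataset's metadata columns.
#' @export
compute_all <- function(dataset, registry = feature_registry(fs = dataset$fs)) {
  .assert(n_windows(dataset) > 0, "dataset is empty")
  d <- dim(dataset$windows)
  nf <- length(registry$output_names)
  vals <- array(NA_real_, dim = c(d[3], d[1], nf),
                dimnames = list(NULL, NULL, registry$output_names))
  for (w in seq_len(d[3])) {
    for (ch in seq_len(d[1])) {
      x <- dataset$windows[ch, , w]
      o <- 1L
      for (s in registry$entries) {
        vals[w, ch, o:(o + s$n_outputs - 1L)] <- compute_feature(s, x)
        o <- o + s$n_outputs
      }
    }
  }
  feature_table(vals, dataset$meta, registry$output_groups)
}

#' Construct a feature table
#'
#' @param values array `n_windows x n_channels x n_features` (dimnames on
#'   the third margin are the feature ids).
#' @param meta data frame with `participant`, `gesture`, `cycle`.
#' @param groups character vector of per-feature group/block labels.
#' @export
feature_table <- function(values, meta, groups) {
  .assert(dim(values)[1] == nrow(meta), "values/meta mismatch")
  structure(list(values = values, meta = meta, groups = groups),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<feature_table> %d windows x %d channels x %d features\n",
              d[1], d[2], d[3]))
  invisible(x)
}

#' Feature ids of a feature table
#' @param table a `feature_table`.
#' @export
feature_ids <- function(table) dimnames(table$values)[[3]]

#' Export a feature table as a wide CSV
#'
#' Columns are `<FEATURE>_c<channel>` plus the metadata columns.
#'
#' @param table a `feature_table`.
#' @param path output CSV path.
#' @export
write_feature_table <- function(table, path) {
  d <- dim(table$values)
  wide <- matrix(table$values, nrow = d[1], ncol = d[2] * d[3])
  colnames(wide) <- as.vector(outer(seq_len(d[2]), feature_ids(table),
                                    function(ch, f) paste0(f, "_c", ch)))
  utils::write.csv(cbind(table$meta, as.data.frame(wide)), path,
                   row.names = FALSE)
  invisible(path)
}

#' Export a registry description as JSON
#' @param registry a [feature_registry()].
#' @param path output JSON path.
#' @export
write_registry_schema <- function(registry, path) {
  entries <- lapply(registry$entries, function(s) {
    list(name = s$name, group = s$group, n_outputs = s$n_outputs,
         params = s$params[setdiff(names(s$params), "fs")])
  })
  jsonlite::write_json(unname(entries), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
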