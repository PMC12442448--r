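# Closed-form reductions of the wet-lab readouts: DSC crystallinity,
# residual activity, total product release.

#' Percent crystallinity from DSC enthalpies
#'
#' `((dHf - dHc) / dHf_100) * 100`, with the fusion enthalpy of fully
#' crystalline PET defaulting to 140 J/g. Values outside `[0, 100]` are
#' physically suspect (DSC baseline excursions) and are returned with a
#' warning and attribute `nonphysical = TRUE` rather than an error.
#'
#' @param dHf_sample enthalpy of fusion of the sample (J/g).
#' @param dHc_sample enthalpy of crystallization from the first heating
#'   curve (J/g).
#' @param dHf_100 enthalpy of fusion of the 100% crystalline polymer (J/g).
#' @return percent crystallinity.
#' @export
crystallinity <- function(dHf_sample, dHc_sample, dHf_100 = 140) {
  if (dHf_100 <= 0)
    pt_abort("dHf_100 must be positive", "petasetyper_input_error")
  pct <- (dHf_sample - dHc_sample) / dHf_100 * 100
  if (pct < 0 || pct > 100) {
    warning("crystallinity outside [0, 100]: check DSC baselines")
    attr(pct, "nonphysical") <- TRUE
  }
  pct
}

#' Residual activity as percent of the time-zero rate
#'
#' `100 * rate_t / rate_0`, the usual normalization of initial hydrolysis
#' rates against the unincubated enzyme.
#'
#' @param rate_t initial rate after incubation.
#' @param rate_0 initial rate at 0 h incubation (must be positive).
#' @return percent residual activity.
#' @export
residual_activity <- function(rate_t, rate_0) {
  if (!is.finite(rate_0) || rate_0 <= 0)
    pt_abort("rate_0 must be positive for normalization",
             "petasetyper_normalization_error")
  100 * rate_t / rate_0
}

#' Total product release
#'
#' Sum of the soluble PET hydrolysis products BHET, MHET and TPA, in one
#' consistent concentration unit. Note that summing molar concentrations
#' counts terephthalate moieties, not mass.
#'
#' @param bhet,mhet,tpa non-negative concentrations in the same unit.
#' @return their sum.
#' @export
total_product_release <- function(bhet, mhet, tpa) {
  vals <- c(bhet, mhet, tpa)
  if (any(!is.finite(vals)) || any(vals < 0))
    pt_abort("product concentrations must be non-negative", "petasetyper_input_error")
  bhet + mhet + tpa
}

#' Read a long-format assay table
#'
#' CSV with columns `sample`, `quantity`, `value`, `unit`. An error is raised
#' if one quantity is reported in different units across rows.
#'
#' @param path CSV path.
#' @return data.frame.
#' @export
read_assay_csv <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("sample", "quantity", "value", "unit")
  if (!all(need %in% names(tab)))
    pt_abort("assay CSV needs columns sample/quantity/value/unit",
             "petasetyper_format_error")
  units <- tapply(tab$unit, tab$quantity, function(u) length(unique(u)))
  if (any(units > 1L))
    pt_abort(sprintf("mixed units for quantity '%s'",
                     names(units)[which(units > 1L)[1L]]),
             "petasetyper_input_error")
  tab
}

#' Total product release per sample from an assay table
#'
#' @param tab a [read_assay_csv()] table carrying quantities `bhet`, `mhet`
#'   and `tpa` per sample.
#' @return data.frame `sample`, `total`, `unit`.
#' @export
total_product_table <- function(tab) {
  out <- lapply(split(tab, tab$sample), function(d) {
    get <- function(q) {
      v <- d$value[d$quantity == q]
      if (!length(v)) 0 else sum(v)
    }
    data.frame(sample = d$sample[1L],
               total = total_product_release(get("bhet"), get("mhet"), get("tpa")),
               unit = d$unit[1L], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out
}
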