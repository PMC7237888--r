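# Fitness-cost proxy for secreted factors.
#
# For each endocrine/exocrine system we tabulate the physiological proxy
# variable the secreted factor controls (e.g. blood glucose for insulin), its
# normal level, and the acutely lethal low and high levels. The fold-distances
# from normal to each lethal bound, mapped into hormone-secretion space via
# the factor's direction of action, give F_hypo and F_hyper; the index
# C = log10(F_hypo/F_hyper) predicts which tissues evolve surveillance
# (C > 0: hypersecretion is the more dangerous failure -> autoimmune-prone)
# and which instead show mutant-expansion disease (C < 0).

#' A cost-proxy record for one secreted factor
#'
#' @param system Label for the hormone/system (e.g. `"insulin"`, `"PTH"`).
#' @param proxy_variable The physiological variable used as proxy (e.g.
#'   `"blood glucose"`).
#' @param scale `"linear"` or `"log10"`. Use `"log10"` when the proxy is
#'   already a log quantity (stomach pH): fold-changes are then computed as
#'   `10^|delta|` of the log-units, since ratios of a log quantity are
#'   meaningless.
#' @param normal,lethal_low,lethal_high Proxy levels with
#'   `lethal_low < normal < lethal_high` on the proxy's monotone scale. On a
#'   linear scale all three must be positive.
#' @param direction `"up"` if hypersecretion of the factor pushes the proxy up
#'   (PTH raises calcium), `"down"` if it pushes it down (insulin lowers
#'   glucose, acid lowers pH).
#' @param observed_class `"autoimmune"`, `"mutant_expansion"` or `"unknown"`.
#' @return A list of class `cost_proxy_record`.
#' @examples
#' cost_proxy_record("insulin", "blood glucose", "linear",
#'                   normal = 5, lethal_low = 3, lethal_high = 14,
#'                   direction = "down", observed_class = "autoimmune")
#' @export
cost_proxy_record <- function(system, proxy_variable, scale = c("linear", "log10"),
                              normal, lethal_low, lethal_high,
                              direction = c("up", "down"),
                              observed_class = c("unknown", "autoimmune",
                                                 "mutant_expansion")) {
  scale <- match.arg(scale)
  if (length(direction) != 1L || !direction %in% c("up", "down")) {
    stop("`direction` must be \"up\" or \"down\"", call. = FALSE)
  }
  observed_class <- match.arg(observed_class)
  stopifnot(is.numeric(normal), is.numeric(lethal_low), is.numeric(lethal_high))
  if (!(lethal_low < normal && normal < lethal_high)) {
    stop("need lethal_low < normal < lethal_high on the proxy scale",
         call. = FALSE)
  }
  if (scale == "linear" && any(c(normal, lethal_low, lethal_high) <= 0)) {
    stop("linear-scale proxy levels must be positive", call. = FALSE)
  }
  structure(list(system = system, proxy_variable = proxy_variable,
                 scale = scale, normal = normal, lethal_low = lethal_low,
                 lethal_high = lethal_high, direction = direction,
                 observed_class = observed_class),
            class = "cost_proxy_record")
}

#' Fold-margins from normal to the lethal bounds, in proxy space
#'
#' On a linear scale, `F_low = normal/lethal_low` and
#' `F_high = lethal_high/normal`. On a log10 scale the margins are
#' `10^(normal - lethal_low)` and `10^(lethal_high - normal)`.
#'
#' @param rec A [cost_proxy_record()].
#' @return Named list `F_low`, `F_high` (each `>= 1`).
#' @examples
#' ca <- cost_proxy_record("PTH", "ionized calcium", "linear",
#'                         1.2, 0.9, 2.5, "up", "mutant_expansion")
#' fold_margins(ca) # F_low ~ 1.3, F_high ~ 2.1
#' @export
fold_margins <- function(rec) {
  stopifnot(inherits(rec, "cost_proxy_record"))
  if (rec$scale == "linear") {
    list(F_low = rec$normal / rec$lethal_low,
         F_high = rec$lethal_high / rec$normal)
  } else {
    list(F_low = 10^(rec$normal - rec$lethal_low),
         F_high = 10^(rec$lethal_high - rec$normal))
  }
}

#' Map proxy-space margins to hormone-secretion space and classify
#'
#' If the factor pushes its proxy up, hypersecretion drives the proxy toward
#' its high lethal bound (`F_hyper = F_high`); if it pushes it down,
#' hypersecretion drives the proxy toward the low bound (`F_hyper = F_low`).
#' The index is `C = log10(F_hypo / F_hyper)`; `C > 0` (hypersecretion is the
#' nearer catastrophe) predicts autoimmune surveillance, `C <= 0` predicts
#' mutant-expansion disease.
#'
#' @param rec A [cost_proxy_record()].
#' @return A list of class `cost_proxy_result`: `system`, `F_hypo`, `F_hyper`,
#'   `C`, `predicted_class`, `observed_class`.
#' @examples
#' ins <- cost_proxy_record("insulin", "blood glucose", "linear",
#'                          5, 3, 14, "down", "autoimmune")
#' hormone_margins(ins)$predicted_class # "autoimmune"
#' @export
hormone_margins <- function(rec) {
  m <- fold_margins(rec)
  if (rec$direction == "up") {
    F_hyper <- m$F_high; F_hypo <- m$F_low
  } else {
    F_hyper <- m$F_low; F_hypo <- m$F_high
  }
  C <- log10(F_hypo / F_hyper)
  structure(list(system = rec$system,
                 F_hypo = F_hypo, F_hyper = F_hyper, C = C,
                 predicted_class = if (C > 0) "autoimmune" else "mutant_expansion",
                 observed_class = rec$observed_class),
            class = "cost_proxy_result")
}

#' Classify a set of cost-proxy records and summarize agreement
#'
#' @param records List of [cost_proxy_record()]s.
#' @return A list with `table` (tibble: system, F_hypo, F_hyper, C,
#'   predicted_class, observed_class, agrees) and `agreement`
#'   (list `n_agree`, `n_scored`; records with unknown observed class are
#'   excluded from the denominator).
#' @examples
#' classify_all(read_cost_proxy_records())$agreement
#' @export
classify_all <- function(records) {
  stopifnot(length(records) > 0)
  rows <- lapply(records, function(r) {
    res <- hormone_margins(r)
    tibble::tibble(system = res$system, F_hypo = res$F_hypo,
                   F_hyper = res$F_hyper, C = res$C,
                   predicted_class = res$predicted_class,
                   observed_class = res$observed_class,
                   agrees = ifelse(res$observed_class == "unknown", NA,
                                   res$predicted_class == res$observed_class))
  })
  tab <- dplyr::bind_rows(rows)
  scored <- !is.na(tab$agrees)
  list(table = tab,
       agreement = list(n_agree = sum(tab$agrees[scored]),
                        n_scored = sum(scored)))
}

#' Read cost-proxy records from CSV
#'
#' Expects columns `system, proxy_variable, scale, normal, lethal_low,
#' lethal_high, direction, observed_class`. Called with no argument it loads
#' the packaged six-system table (PTH/calcium, insulin and glucagon/glucose,
#' renin/systolic blood pressure, thyroxine/free T4, gastric acid/stomach pH).
#'
#' @param path CSV path; default the packaged fixture.
#' @return A list of [cost_proxy_record()]s.
#' @export
read_cost_proxy_records <- function(path = system.file("extdata",
                                                       "cost_proxy_systems.csv",
                                                       package = "ashm")) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  needed <- c("system", "proxy_variable", "scale", "normal", "lethal_low",
              "lethal_high", "direction", "observed_class")
  missing <- setdiff(needed, names(df))
  if (length(missing)) {
    stop("cost-proxy CSV lacks columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  lapply(seq_len(nrow(df)), function(i) {
    cost_proxy_record(df$system[i], df$proxy_variable[i], df$scale[i],
                      df$normal[i], df$lethal_low[i], df$lethal_high[i],
                      df$direction[i], df$observed_class[i])
  })
}
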