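#' Half-turn morphometry table
#'
#' Container for the radial widths of Reissner's membrane (RM) and of the
#' organ of Corti (OC) and the longitudinal (baso-apical) length of each
#' cochlear segment. The guinea-pig cochlea is described by 8.5 half-turns:
#' the basal hook region plus half-turns I (base) to VIII (apex).
#'
#' @param label character vector of segment labels; must be exactly
#'   `c("hook", "I", ..., "VIII")` in base-to-apex order.
#' @param w_rm_um radial width of Reissner's membrane per half-turn (um).
#'   The hook row carries `NA`: the hook area uses the half-turn I width.
#' @param w_oc_um radial width of the organ of Corti per half-turn (um),
#'   same convention.
#' @param l_um longitudinal length of each segment including the hook (um).
#' @return A `data.frame` of class `half_turn_table`.
#' @seealso [compute_partition_areas()], [read_half_turn_csv()]
#' @export
half_turn_table <- function(label, w_rm_um, w_oc_um, l_um) {
  tab <- data.frame(label = as.character(label),
                    w_rm_um = as.numeric(w_rm_um),
                    w_oc_um = as.numeric(w_oc_um),
                    l_um = as.numeric(l_um),
                    stringsAsFactors = FALSE)
  validate_half_turn_table(tab)
}

SEGMENT_LABELS <- c("hook", "I", "II", "III", "IV", "V", "VI", "VII", "VIII")

validate_half_turn_table <- function(tab) {
  if (!identical(tab$label, SEGMENT_LABELS)) {
    missing <- setdiff(SEGMENT_LABELS, tab$label)
    if (length(missing)) {
      stop_validation("half-turn table is missing segment(s): %s",
                      paste(missing, collapse = ", "))
    }
    stop_validation("segment labels must be %s in base-to-apex order",
                    paste(SEGMENT_LABELS, collapse = ", "))
  }
  check_positive(tab$l_um, "l_um")
  for (col in c("w_rm_um", "w_oc_um")) {
    w <- tab[[col]][-1]  # hook row may be NA (uses half-turn I width)
    if (anyNA(w) || any(w <= 0)) {
      bad <- tab$label[-1][is.na(w) | w <= 0]
      stop_validation("non-positive or missing %s in segment(s): %s",
                      col, paste(bad, collapse = ", "))
    }
  }
  class(tab) <- c("half_turn_table", "data.frame")
  tab
}

#' Read / write a half-turn morphometry table as CSV
#'
#' Columns: `segment` (0-based index), `label`, `w_RM_um`, `w_OC_um`,
#' `l_um`; one header row, UTF-8, `.` decimal separator.
#'
#' @param path file path.
#' @return [read_half_turn_csv()] returns a `half_turn_table`.
#' @export
read_half_turn_csv <- function(path) {
  raw <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("label", "w_RM_um", "w_OC_um", "l_um")
  if (!all(need %in% names(raw))) {
    stop_validation("half-turn CSV must have columns %s",
                    paste(need, collapse = ", "))
  }
  half_turn_table(raw$label, raw$w_RM_um, raw$w_OC_um, raw$l_um)
}

#' @rdname read_half_turn_csv
#' @param table a `half_turn_table`.
#' @export
write_half_turn_csv <- function(table, path) {
  stopifnot(inherits(table, "half_turn_table"))
  out <- data.frame(segment = seq_len(nrow(table)) - 1L,
                    label = table$label,
                    w_RM_um = table$w_rm_um,
                    w_OC_um = table$w_oc_um,
                    l_um = table$l_um)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Surface area of one barrier partition by the trapezoid rule
#'
#' Each half-turn contributes a trapezoid A_i = l_i * (w_i + w_{i+1}) / 2,
#' where w_i and w_{i+1} are the widths at the basal and apical end of the
#' segment. The two unbounded ends are rectangles: the hook uses the
#' half-turn I width (w_I * l_hook) and the apical-most half-turn VIII,
#' which has no apical neighbour, uses its own width at both ends
#' (w_VIII * l_VIII).
#'
#' @param table a [half_turn_table()].
#' @param partition `"RM"` (Reissner's membrane, the scala-vestibuli-facing
#'   partition) or `"OC"` (organ of Corti, scala-tympani-facing).
#' @return Object of class `barrier_areas`: per-segment areas and the
#'   total, in mm^2 (internally also carried in cm^2).
#' @export
compute_partition_areas <- function(table, partition = c("RM", "OC")) {
  table <- validate_half_turn_table(as.data.frame(table))
  partition <- match.arg(partition)
  w_um <- if (partition == "RM") table$w_rm_um else table$w_oc_um
  l_um <- table$l_um
  n <- nrow(table)  # 9: hook + I..VIII

  a_um2 <- numeric(n)
  a_um2[1] <- w_um[2] * l_um[1]                      # hook: rectangle at w_I
  for (i in 2:(n - 1L)) {
    a_um2[i] <- l_um[i] * (w_um[i] + w_um[i + 1L]) / 2
  }
  a_um2[n] <- w_um[n] * l_um[n]                      # apex: rectangle at w_VIII

  a_mm2 <- um2_to_mm2(a_um2)
  structure(list(partition = partition,
                 label = table$label,
                 per_segment_mm2 = a_mm2,
                 total_mm2 = sum(a_mm2),
                 total_cm2 = mm2_to_cm2(sum(a_mm2))),
            class = "barrier_areas")
}

#' Areas of all perilymph-endolymph barrier partitions
#'
#' Convenience wrapper computing A_SV/SM (RM partition), A_ST/SM (OC
#' partition) and their sum A_SV+ST/SM, which by construction is exactly
#' additive.
#'
#' @inheritParams compute_partition_areas
#' @return A list with components `rm`, `oc` (both `barrier_areas`) and
#'   `totals_mm2` = c(A_SV_SM, A_ST_SM, A_SV_ST_SM).
#' @export
compute_barrier_areas <- function(table) {
  rm_a <- compute_partition_areas(table, "RM")
  oc_a <- compute_partition_areas(table, "OC")
  list(rm = rm_a, oc = oc_a,
       totals_mm2 = c(A_SV_SM_mm2 = rm_a$total_mm2,
                      A_ST_SM_mm2 = oc_a$total_mm2,
                      A_SV_ST_SM_mm2 = rm_a$total_mm2 + oc_a$total_mm2))
}

#' @export
print.barrier_areas <- function(x, ...) {
  cat(sprintf("Barrier partition %s: total %.4f mm^2\n", x$partition, x$total_mm2))
  print(data.frame(segment = x$label, area_mm2 = signif(x$per_segment_mm2, 6)))
  invisible(x)
}

#' Summary statistics for replicate measurements
#'
#' Arithmetic mean and sample standard deviation (n - 1 denominator) of a
#' set of replicate length measurements, as tabulated for the per-specimen
#' immunofluorescence extents.
#'
#' @param values numeric vector of replicate measurements (um); `n >= 1`,
#'   the standard deviation is defined only for `n >= 2` (otherwise `NA`).
#' @return Object of class `replicate_set`: `values`, `n`, `mean`, `sd`.
#' @export
summarize_replicates <- function(values) {
  if (length(values) == 0L || !is.numeric(values) || anyNA(values)) {
    stop_validation("replicate values must be a non-empty numeric vector")
  }
  structure(list(values = as.numeric(values),
                 n = length(values),
                 mean = mean(values),
                 sd = if (length(values) >= 2L) stats::sd(values) else NA_real_),
            class = "replicate_set")
}

#' @export
print.replicate_set <- function(x, ...) {
  cat(sprintf("n = %d, mean = %.2f, sd = %s\n", x$n, x$mean,
              if (is.na(x$sd)) "NA (n < 2)" else sprintf("%.2f", x$sd)))
  invisible(x)
}

#' Shunt membrane area of the apical outer sulcus cells
#'
#' The aquaporin-4/aquaporin-5 co-expressing outer sulcus cells in the
#' apical half-turn form a rectangular membrane patch: radial width of the
#' apical membranes times the longitudinal extent of co-expression.
#'
#' @param radial_width_um radial width (um), e.g. the mean AQP5 width.
#' @param longitudinal_length_um baso-apical length (um) of co-expression.
#' @return Object of class `shunt_membrane_area` with the product in um^2
#'   and mm^2.
#' @export
compute_shunt_area <- function(radial_width_um, longitudinal_length_um) {
  check_positive(radial_width_um, "radial_width_um")
  check_positive(longitudinal_length_um, "longitudinal_length_um")
  a_um2 <- radial_width_um * longitudinal_length_um
  structure(list(radial_width_um = radial_width_um,
                 longitudinal_length_um = longitudinal_length_um,
                 area_um2 = a_um2,
                 area_mm2 = um2_to_mm2(a_um2)),
            class = "shunt_membrane_area")
}

#' @export
print.shunt_membrane_area <- function(x, ...) {
  cat(sprintf("%.2f um x %.2f um = %.2f um^2 (%.5f mm^2)\n",
              x$radial_width_um, x$longitudinal_length_um,
              x$area_um2, x$area_mm2))
  invisible(x)
}

#' JSON report of barrier areas
#'
#' @param areas result of [compute_barrier_areas()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_areas_json <- function(areas, path) {
  per_segment <- data.frame(segment = areas$rm$label,
                            A_RM_mm2 = areas$rm$per_segment_mm2,
                            A_OC_mm2 = areas$oc$per_segment_mm2)
  jsonlite::write_json(list(per_segment = per_segment,
                            totals = as.list(areas$totals_mm2)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
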