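#' Chloroplast size classes
#'
#' Plastid bodies are binned by length into three classes: mini (< 2 um),
#' normal (2-6 um, both bounds included) and giant (> 6 um). The half-open
#' convention keeps the giant class strictly above 6 um, so a 6.0 um
#' chloroplast is normal and a 6.8 um one is giant.
#'
#' @return `size_classes()` returns the ordered class labels, smallest first.
#' @export
size_classes <- function() c("mini", "normal", "giant")

#' Guard-cell type labels
#'
#' Guard cells (GCs) are typed by their chloroplast content: type 1 holds at
#' least one giant chloroplast; type 2 holds normal-sized chloroplasts but no
#' giant; type 3 holds no chloroplast at all. A fourth, out-of-taxonomy label
#' `"mini_only"` marks GCs whose only chloroplasts are mini-class — a
#' configuration never observed in leaf stomata and therefore flagged rather
#' than silently folded into the three types.
#'
#' @return Character vector of the four labels.
#' @export
gc_type_labels <- function() c("type1", "type2", "type3", "mini_only")

#' Guard-cell plastid-population morphology classes
#'
#' @return Labels `"I"`-`"IV"`: I = homogeneous normal-sized chlorophyllous
#'   plastids; II = abnormal mixed population (residual class); III = all
#'   plastids mini and chlorophyll-less; IV = web-like, entirely tubulated
#'   chlorophyll-less structures (any reticulate plastid).
#' @export
morph_class_labels <- function() c("I", "II", "III", "IV")

#' Classify chloroplast length into a size class
#'
#' @param length_um Numeric vector of plastid body lengths in micrometres;
#'   all values must be finite and positive.
#' @return Factor with levels `mini < normal < giant`.
#' @examples
#' classify_size(c(6.8, 4.3, 1.0, 6, 2))
#' @export
classify_size <- function(length_um) {
  if (!is.numeric(length_um)) {
    abort("`length_um` must be numeric.")
  }
  bad <- !is.finite(length_um) | length_um <= 0
  if (any(bad)) {
    abort(sprintf(
      "plastid lengths must be finite and positive; offending values: %s",
      paste(head(format(length_um[bad]), 5), collapse = ", ")
    ))
  }
  out <- ifelse(length_um > 6, "giant", ifelse(length_um >= 2, "normal", "mini"))
  factor(out, levels = size_classes())
}

#' Is a plastid a chloroplast?
#'
#' A plastid counts as a chloroplast when chlorophyll autofluorescence was
#' detected. Status is an input annotation, never inferred from size.
#'
#' @param chlorophyllous Logical (or 0/1) vector.
#' @return Logical vector.
#' @export
is_chloroplast <- function(chlorophyllous) {
  out <- as.logical(chlorophyllous)
  if (any(is.na(out))) abort("`chlorophyllous` contains missing values.")
  out
}

#' Type a single guard cell from its plastid measurements
#'
#' Applies the three-type taxonomy to one GC's plastid collection: type 1 if
#' any chlorophyllous plastid is giant, else type 2 if any chlorophyllous
#' plastid is normal-sized, else type 3 if no plastid is chlorophyllous.
#' A GC whose only chloroplasts are mini receives the out-of-taxonomy label
#' `"mini_only"` with a warning, preserving the empirical claim that such
#' cells do not occur as a data-quality check.
#'
#' @param length_um,chlorophyllous Parallel vectors describing one GC's
#'   plastids.
#' @param permissive If `TRUE`, an empty plastid collection is labelled
#'   `"type3"` with a warning instead of erroring. GCs devoid of plastids
#'   were never detected, so the strict default treats them as invalid.
#' @return Length-1 factor with levels [gc_type_labels()].
#' @examples
#' classify_gc_type(c(7.2, 3.0), c(TRUE, TRUE))   # type1
#' classify_gc_type(rep(1.5, 20), rep(FALSE, 20)) # type3
#' @export
classify_gc_type <- function(length_um, chlorophyllous, permissive = FALSE) {
  lv <- gc_type_labels()
  if (length(length_um) == 0) {
    if (permissive) {
      warn("GC with no plastids labelled type3 (permissive mode).")
      return(factor("type3", levels = lv))
    }
    abort("GC has no plastids (NoPlastids); use `permissive = TRUE` to label it type3.")
  }
  chl <- is_chloroplast(chlorophyllous)
  sz <- classify_size(length_um)
  type <-
    if (any(chl & sz == "giant")) {
      "type1"
    } else if (any(chl & sz == "normal")) {
      "type2"
    } else if (!any(chl)) {
      "type3"
    } else {
      warn("GC contains only mini-class chloroplasts: labelled 'mini_only' (out of taxonomy).")
      "mini_only"
    }
  factor(type, levels = lv)
}

#' Morphology class of a single guard cell
#'
#' Class IV if any plastid is reticulate (part of a web-like, entirely
#' tubulated structure); else III if every plastid is mini and
#' chlorophyll-less; else I if every plastid is normal-sized and
#' chlorophyllous; otherwise the residual class II.
#'
#' @inheritParams classify_gc_type
#' @param reticulate Logical (or 0/1) vector parallel to `length_um`.
#' @return Length-1 factor with levels [morph_class_labels()].
#' @export
classify_morph_class <- function(length_um, chlorophyllous, reticulate,
                                 permissive = FALSE) {
  lv <- morph_class_labels()
  if (length(length_um) == 0) {
    if (permissive) {
      warn("GC with no plastids labelled class III (permissive mode).")
      return(factor("III", levels = lv))
    }
    abort("GC has no plastids (NoPlastids).")
  }
  chl <- is_chloroplast(chlorophyllous)
  ret <- as.logical(reticulate)
  if (any(is.na(ret))) abort("`reticulate` contains missing values.")
  if (any(ret & chl)) {
    abort("reticulate plastids must be chlorophyll-less.")
  }
  sz <- classify_size(length_um)
  cls <-
    if (any(ret)) {
      "IV"
    } else if (all(sz == "mini") && !any(chl)) {
      "III"
    } else if (all(sz == "normal") && all(chl)) {
      "I"
    } else {
      "II"
    }
  factor(cls, levels = lv)
}

#' Classify every guard cell of a plastid table
#'
#' Groups a tidy plastid table (one row per plastid; see
#' [read_plastid_table()] for the schema) by guard cell and applies
#' [classify_gc_type()] and [classify_morph_class()] to each.
#'
#' @param plastids Tibble with columns `line`, `stoma_id`, `gc_id`,
#'   `length_um`, `chlorophyllous`, `reticulate`.
#' @param permissive Passed on to the per-GC classifiers.
#' @return Tibble with one row per GC: identifiers, `n_plastids`,
#'   `n_chloroplasts`, `gc_type` and `morph_class`.
#' @export
classify_gcs <- function(plastids, permissive = FALSE) {
  required <- c("line", "stoma_id", "gc_id", "length_um", "chlorophyllous", "reticulate")
  missing <- setdiff(required, names(plastids))
  if (length(missing) > 0) {
    abort(paste0("plastid table lacks column(s): ", paste(missing, collapse = ", ")))
  }
  plastids %>%
    group_by(.data$line, .data$stoma_id, .data$gc_id) %>%
    summarise(
      n_plastids = n(),
      n_chloroplasts = sum(is_chloroplast(.data$chlorophyllous)),
      gc_type = classify_gc_type(.data$length_um, .data$chlorophyllous,
                                 permissive = permissive),
      morph_class = classify_morph_class(.data$length_um, .data$chlorophyllous,
                                         .data$reticulate, permissive = permissive),
      .groups = "drop"
    )
}
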