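#' Canonical 14-muscle registry
#'
#' The analysis records 14 surface-EMG channels per body side. This registry
#' fixes their canonical order, maps each muscle to a limb/body segment
#' (crus, thigh or trunk), and carries the alias table used when ingesting
#' files with vendor-specific channel labels.
#'
#' @param segment_overrides optional named character vector reassigning
#'   muscles to segments, e.g. `c(GM = "trunk")`. The default places the
#'   gluteus maximus with the thigh muscles, giving the 4/7/3
#'   crus/thigh/trunk partition.
#' @return An object of class `MuscleRegistry`: a list with `names` (ordered
#'   muscle labels), `segment_map` (named character vector) and `aliases`
#'   (named character vector mapping accepted alternative labels to canonical
#'   ones).
#' @examples
#' reg <- muscle_registry()
#' reg$names
#' reg$segment_map[["TA"]]
#' @export
muscle_registry <- function(segment_overrides = NULL) {
  names <- c("TA", "MG", "LG", "Sol", "VL", "VM", "RF", "Ham",
             "AL", "TFL", "GM", "ES", "ExtO", "LatDor")
  segment_map <- c(
    TA = "crus", MG = "crus", LG = "crus", Sol = "crus",
    VL = "thigh", VM = "thigh", RF = "thigh", Ham = "thigh",
    AL = "thigh", TFL = "thigh", GM = "thigh",
    ES = "trunk", ExtO = "trunk", LatDor = "trunk"
  )
  if (!is.null(segment_overrides)) {
    bad <- setdiff(names(segment_overrides), names)
    if (length(bad)) stop("unknown muscles in segment_overrides: ",
                          paste(bad, collapse = ", "))
    if (!all(segment_overrides %in% c("crus", "thigh", "trunk")))
      stop("segments must be one of crus, thigh, trunk")
    segment_map[names(segment_overrides)] <- segment_overrides
  }
  aliases <- c(
    "TibAnt" = "TA", "TibialisAnterior" = "TA",
    "Gastroc-Med" = "MG", "GastrocMed" = "MG", "MedGas" = "MG",
    "Gastroc-Lat" = "LG", "GastrocLat" = "LG", "LatGas" = "LG",
    "Soleus" = "Sol",
    "VastLat" = "VL", "VastusLateralis" = "VL",
    "VastMed" = "VM", "VastusMedialis" = "VM",
    "RectFem" = "RF", "RectusFemoris" = "RF",
    "Hamstrings" = "Ham", "BF" = "Ham",
    "AddLong" = "AL", "AdductorLongus" = "AL",
    "TensorFL" = "TFL",
    "GlutMax" = "GM", "GluteusMaximus" = "GM",
    "ErSp" = "ES", "ErectorSpinae" = "ES",
    "ExtObl" = "ExtO", "ExternalOblique" = "ExtO",
    "LatDorsi" = "LatDor", "LatissimusDorsi" = "LatDor"
  )
  structure(list(names = names, segment_map = segment_map, aliases = aliases),
            class = "MuscleRegistry")
}

#' Resolve muscle labels against the registry
#'
#' Maps raw channel labels (canonical names or registered aliases) to
#' canonical names; unknown labels are an error so that silent column
#' misassignment can never corrupt downstream synergies.
#'
#' @param labels character vector of channel labels.
#' @param registry a [muscle_registry()].
#' @return character vector of canonical labels, same length as `labels`.
#' @export
resolve_muscles <- function(labels, registry = muscle_registry()) {
  out <- character(length(labels))
  for (i in seq_along(labels)) {
    lab <- trimws(labels[i])
    if (lab %in% registry$names) {
      out[i] <- lab
    } else if (lab %in% names(registry$aliases)) {
      out[i] <- registry$aliases[[lab]]
    } else {
      stop("unknown muscle label '", lab, "'; accepted labels: ",
           paste(registry$names, collapse = ", "),
           "; accepted aliases: ",
           paste(names(registry$aliases), collapse = ", "), call. = FALSE)
    }
  }
  if (anyDuplicated(out))
    stop("duplicate muscle labels after alias resolution: ",
         paste(unique(out[duplicated(out)]), collapse = ", "), call. = FALSE)
  out
}

#' @export
print.MuscleRegistry <- function(x, ...) {
  cat("MuscleRegistry:", length(x$names), "muscles\n")
  for (seg in c("crus", "thigh", "trunk"))
    cat(sprintf("  %-5s: %s\n", seg,
                paste(x$names[x$segment_map[x$names] == seg], collapse = ", ")))
  invisible(x)
}
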