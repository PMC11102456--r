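# fROI registry: the 9 bilateral category-selective regions of the ventral
# visual stream and their localizer contrasts.

#' Stimulus conditions of the dynamic localizer
#'
#' @return character vector of the five stimulus conditions.
#' @export
localizer_conditions <- function() {
  c("faces", "bodies", "scenes", "objects", "scrambled")
}

#' Registry of category-selective fROIs
#'
#' Nine bilateral regions (18 total): three face regions (FFA, OFA, STS), one
#' body region (EBA), three scene regions (PPA, RSC, TOS) and two object
#' regions (LO, PFS). Each entry records its preferred category and the
#' contrast category used to localize it (objects for face/body/scene
#' regions, scrambled objects for object regions).
#'
#' @return data.frame with columns `froi` (e.g. "rFFA"), `name`, `hemi`,
#'   `category`, `preferred_condition`, `contrast_condition`, `search_space`.
#' @export
froi_registry <- function() {
  names9 <- c("FFA", "OFA", "STS", "EBA", "PPA", "RSC", "TOS", "LO", "PFS")
  cat9 <- c("face", "face", "face", "body", "scene", "scene", "scene",
            "object", "object")
  pref9 <- c("faces", "faces", "faces", "bodies", "scenes", "scenes",
             "scenes", "objects", "objects")
  con9 <- c(rep("objects", 7), rep("scrambled", 2))
  out <- do.call(rbind, lapply(c("left", "right"), function(h) {
    data.frame(
      froi = paste0(substr(h, 1, 1), names9),
      name = names9,
      hemi = h,
      category = cat9,
      preferred_condition = pref9,
      contrast_condition = con9,
      stringsAsFactors = FALSE
    )
  }))
  out$search_space <- out$froi
  rownames(out) <- NULL
  out
}

#' Preferred categories with fROI representation
#' @return character vector c("face","body","scene","object").
#' @keywords internal
froi_categories <- function() c("face", "body", "scene", "object")

# condition name driving each category's selectivity field
category_condition <- function(category) {
  map <- c(face = "faces", body = "bodies", scene = "scenes", object = "objects")
  unname(map[category])
}
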