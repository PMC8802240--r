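## Controlled vocabulary for the categorical reproductive traits. Loaders
## validate against these levels; "missing" is encoded as NA throughout.
trait_vocabulary <- function() {
  list(
    sperm_location    = c("hypodermic", "both", "antrum"),
    bristle_state     = c("absent", "reduced", "present"),
    antrum_state      = c("simple", "thickened"),
    stylet_sharpness  = c("sharp", "neutral", "blunt"),
    brush             = c("absent", "present"),
    velum             = c("absent", "present"),
    n_genital_openings = c("1", "2")
  )
}

#' Load the per-species categorical trait table
#'
#' One row per species. Categorical columns are validated against the
#' controlled vocabulary ([trait_vocabulary()]); an unknown level is an error
#' at load time, never silently coerced. Empty strings and `"NA"` become
#' missing values.
#'
#' @param path CSV file with a `species` column plus any subset of the
#'   vocabulary columns and ordinal antrum component scores
#'   (`antrum_thickness`, `cellular_valve`, `chamber_complexity`).
#' @return A data.frame, one row per species.
#' @export
load_trait_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"species" %in% names(df)) stop("trait table needs a 'species' column")
  if (anyDuplicated(df$species)) stop("duplicated species in trait table")
  vocab <- trait_vocabulary()
  for (col in intersect(names(vocab), names(df))) {
    v <- as.character(df[[col]])
    v[v %in% c("", "NA", "missing")] <- NA
    bad <- setdiff(unique(v[!is.na(v)]), vocab[[col]])
    if (length(bad) > 0L) {
      stop("unknown level(s) in column '", col, "': ",
           paste(bad, collapse = ", "))
    }
    df[[col]] <- v
  }
  df
}

#' Load the per-specimen quantitative measurement table
#'
#' Long format: one row per specimen per trait. All measurements must be
#' strictly positive (they are areas or lengths in micrometres and are
#' log-transformed downstream).
#'
#' @param path CSV file with columns `species`, `trait`, `value` and
#'   optionally `specimen`.
#' @return A data.frame.
#' @export
load_specimen_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("species", "trait", "value")
  if (!all(need %in% names(df))) {
    stop("specimen table needs columns: ", paste(need, collapse = ", "))
  }
  df$value <- as.numeric(df$value)
  bad <- which(!is.finite(df$value) | df$value <= 0)
  if (length(bad) > 0L) {
    stop("non-positive or missing measurement at row(s): ",
         paste(utils::head(bad, 5L), collapse = ", "))
  }
  df
}

#' Classify species into inferred mating syndromes
#'
#' Applies the morphology-based decision rules in order; the first rule that
#' fires assigns the label. Direct observation of exclusively hypodermic
#' received sperm is decisive (rule 1); in species without received-sperm
#' observations the hypodermic syndrome is inferred from the full hypodermic
#' morphology (reduced/absent sperm bristles, simple antrum, sharp stylet;
#' rule 2). Sperm in both locations marks the intermediate syndrome (rule 3).
#' Received sperm in the antrum indicates reciprocal mating when the stylet
#' is blunt (rule 4), or when a sharp-styleted species retains sperm bristles
#' (rule 5). Everything else is unclear (rule 6). A trinary "neutral" stylet
#' counts as non-sharp (blunt-like) wherever a rule asks for blunt.
#'
#' @param records Data.frame with columns `species`, `sperm_location`,
#'   `bristle_state`, `antrum_state`, `stylet_sharpness` (missing values
#'   allowed, as `NA`).
#' @return Data.frame with columns `species`, `syndrome` (one of
#'   `"hypodermic"`, `"intermediate"`, `"reciprocal"`, `"unclear"`) and
#'   `rule` (integer id of the rule that fired).
#' @examples
#' rec <- data.frame(species = "sp1", sperm_location = "antrum",
#'                   bristle_state = "absent", antrum_state = "thickened",
#'                   stylet_sharpness = "blunt")
#' classify_syndrome(rec)
#' @export
classify_syndrome <- function(records) {
  need <- c("species", "sperm_location", "bristle_state", "antrum_state",
            "stylet_sharpness")
  missing_cols <- setdiff(need, names(records))
  if (length(missing_cols) > 0L) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  loc <- as.character(records$sperm_location)
  bri <- as.character(records$bristle_state)
  ant <- as.character(records$antrum_state)
  sty <- as.character(records$stylet_sharpness)
  bluntish <- !is.na(sty) & sty %in% c("blunt", "neutral")

  n <- nrow(records)
  label <- rep("unclear", n)
  rule <- rep(6L, n)

  r1 <- !is.na(loc) & loc == "hypodermic"
  r2 <- !r1 & is.na(loc) &
    !is.na(bri) & bri %in% c("reduced", "absent") &
    !is.na(ant) & ant == "simple" &
    !is.na(sty) & sty == "sharp"
  r3 <- !r1 & !r2 & !is.na(loc) & loc == "both"
  r4 <- !r1 & !r2 & !r3 & !is.na(loc) & loc == "antrum" & bluntish
  r5 <- !r1 & !r2 & !r3 & !r4 & !is.na(loc) & loc == "antrum" &
    !is.na(sty) & sty == "sharp" & !is.na(bri) & bri == "present"

  label[r1] <- "hypodermic";   rule[r1] <- 1L
  label[r2] <- "hypodermic";   rule[r2] <- 2L
  label[r3] <- "intermediate"; rule[r3] <- 3L
  label[r4] <- "reciprocal";   rule[r4] <- 4L
  label[r5] <- "reciprocal";   rule[r5] <- 5L

  data.frame(species = as.character(records$species), syndrome = label,
             rule = rule, stringsAsFactors = FALSE)
}

#' Collapse a categorical trait to the binary coding used for Mk analyses
#'
#' Codings follow the convention that state 0 is the hypodermic-like (derived
#' under the loss interpretation) state and state 1 the reciprocal-like
#' state:
#' * `sperm_location`: hypodermic or both -> 0, antrum -> 1 (species with
#'   sperm in both locations are grouped with hypodermic by default; set
#'   `both_as = "exclude"` to drop them instead),
#' * `bristle_state`: absent or reduced -> 0, present -> 1,
#' * `antrum_state`: simple -> 0, thickened -> 1,
#' * `syndrome`: hypodermic or intermediate -> 0, reciprocal -> 1 (unclear
#'   -> `NA`).
#'
#' Missing stays missing: species with `NA` are excluded downstream, never
#' imputed.
#'
#' @param values Character vector of trait values.
#' @param scheme One of `"sperm_location"`, `"bristle_state"`,
#'   `"antrum_state"`, `"syndrome"`.
#' @param both_as How to code `"both"` under `scheme = "sperm_location"`:
#'   `"hypodermic"` (default, coded 0) or `"exclude"` (coded `NA`).
#' @return Integer vector of 0/1/NA.
#' @export
recode_binary <- function(values,
                          scheme = c("sperm_location", "bristle_state",
                                     "antrum_state", "syndrome"),
                          both_as = c("hypodermic", "exclude")) {
  scheme <- match.arg(scheme)
  both_as <- match.arg(both_as)
  v <- as.character(values)
  out <- rep(NA_integer_, length(v))
  map <- switch(scheme,
    sperm_location = c(hypodermic = 0L,
                       both = if (both_as == "hypodermic") 0L else NA_integer_,
                       antrum = 1L),
    bristle_state = c(absent = 0L, reduced = 0L, present = 1L),
    antrum_state = c(simple = 0L, thickened = 1L),
    syndrome = c(hypodermic = 0L, intermediate = 0L, reciprocal = 1L,
                 unclear = NA_integer_)
  )
  known <- !is.na(v) & v %in% names(map)
  bad <- setdiff(unique(v[!is.na(v)]), names(map))
  if (length(bad) > 0L) {
    stop("unknown level(s) for scheme '", scheme, "': ",
         paste(bad, collapse = ", "))
  }
  out[known] <- unname(map[v[known]])
  out
}

#' Recode a trait to the trinary 0/1/2 state space
#'
#' `sperm_location`: hypodermic -> 0, both -> 1, antrum -> 2.
#' `bristle_state`: absent -> 0, reduced -> 1, present -> 2.
#' `syndrome`: hypodermic -> 0, intermediate -> 1, reciprocal -> 2.
#'
#' @inheritParams recode_binary
#' @return Integer vector of 0/1/2/NA.
#' @export
recode_trinary <- function(values,
                           scheme = c("sperm_location", "bristle_state",
                                      "syndrome")) {
  scheme <- match.arg(scheme)
  v <- as.character(values)
  map <- switch(scheme,
    sperm_location = c(hypodermic = 0L, both = 1L, antrum = 2L),
    bristle_state = c(absent = 0L, reduced = 1L, present = 2L),
    syndrome = c(hypodermic = 0L, intermediate = 1L, reciprocal = 2L,
                 unclear = NA_integer_)
  )
  bad <- setdiff(unique(v[!is.na(v)]), names(map))
  if (length(bad) > 0L) {
    stop("unknown level(s) for scheme '", scheme, "': ",
         paste(bad, collapse = ", "))
  }
  out <- rep(NA_integer_, length(v))
  known <- !is.na(v)
  out[known] <- unname(map[v[known]])
  out
}

#' Transform and aggregate per-specimen quantitative measurements
#'
#' Body area is transformed as `log10(sqrt(area))` (a linearised body size);
#' every linear measure as `log10(value)`. Species-level values are the mean
#' of per-specimen transformed values (log first, then average — the
#' variance-stabilising order; `log_first = FALSE` averages raw values and
#' logs the mean instead). Per-trait specimen counts are carried alongside
#' for use as regression weights.
#'
#' @param specimens Long-format data.frame with columns `species`, `trait`,
#'   `value` (strictly positive).
#' @param area_traits Traits treated as areas (square-root before log);
#'   default `"body_area"`.
#' @param log_first Logical; aggregate on the log scale (default) or log the
#'   per-species mean.
#' @return A list with `values` (species x trait matrix of transformed
#'   species means) and `n` (matching matrix of specimen counts).
#' @examples
#' sp <- data.frame(species = "s1", trait = "sperm_length",
#'                  value = c(10, 1000))
#' transform_quantitative(sp)$values  # mean of logs = 2
#' @export
transform_quantitative <- function(specimens, area_traits = "body_area",
                                   log_first = TRUE) {
  bad <- which(!is.finite(specimens$value) | specimens$value <= 0)
  if (length(bad) > 0L) {
    stop("non-positive measurement for species '",
         specimens$species[bad[1L]], "', trait '",
         specimens$trait[bad[1L]], "' (row ", bad[1L], ")")
  }
  species <- sort(unique(as.character(specimens$species)))
  traits <- unique(as.character(specimens$trait))
  vals <- matrix(NA_real_, length(species), length(traits),
                 dimnames = list(species, traits))
  nmat <- matrix(0L, length(species), length(traits),
                 dimnames = list(species, traits))
  trans <- function(x, trait) {
    if (trait %in% area_traits) log10(sqrt(x)) else log10(x)
  }
  for (tr in traits) {
    sub <- specimens[specimens$trait == tr, , drop = FALSE]
    agg_n <- tapply(sub$value, sub$species, length)
    if (log_first) {
      agg <- tapply(trans(sub$value, tr), sub$species, mean)
    } else {
      agg <- trans(tapply(sub$value, sub$species, mean), tr)
    }
    vals[names(agg), tr] <- agg
    nmat[names(agg_n), tr] <- as.integer(agg_n)
  }
  list(values = vals, n = nmat)
}
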