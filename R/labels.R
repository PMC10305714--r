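#' Activity label vocabulary
#'
#' Sixteen driving activities: codes 0--11 are primary manoeuvres (crossroad,
#' parking and roundabout variants) and 12--15 are secondary (distracting)
#' activities.  The type group is derivable from the name prefix.
#'
#' @return A data frame with columns `code`, `name`, `type_group`,
#'   `is_primary`, one row per activity, ordered by code.
#' @export
#' @examples
#' activity_labels()
activity_labels <- function() {
  names <- c(
    "P_Crossroad_Left", "P_Crossroad_Right", "P_Crossroad_Straight",
    "P_Parking_Diagonal_Left", "P_Parking_Diagonal_Right",
    "P_Parking_Parallel_Left", "P_Parking_Parallel_Right",
    "P_Parking_Perpendicular_Left", "P_Parking_Perpendicular_Right",
    "P_Roundabout_Left", "P_Roundabout_Right", "P_Roundabout_Straight",
    "S_Bending", "S_Drinking", "S_Eating", "S_Turning_Back"
  )
  data.frame(
    code = 0:15,
    name = names,
    type_group = type_group_of(names),
    is_primary = startsWith(names, "P_"),
    stringsAsFactors = FALSE
  )
}

#' @rdname activity_labels
#' @export
activity_groups <- function() c("Crossroad", "Parking", "Roundabout", "Secondary")

# Group from the name prefix; secondary names all start with "S_".
type_group_of <- function(name) {
  ifelse(startsWith(name, "S_"), "Secondary",
    ifelse(startsWith(name, "P_Crossroad"), "Crossroad",
      ifelse(startsWith(name, "P_Parking"), "Parking",
        ifelse(startsWith(name, "P_Roundabout"), "Roundabout", NA_character_)
      )
    )
  )
}

#' Look up an activity label by code or name
#'
#' @param code_or_name Integer code in 0--15 or the activity name
#'   (e.g. `"P_Crossroad_Left"`).
#' @return An object of class `activity_label`: a list with fields `code`,
#'   `name`, `type_group` and `is_primary`.
#' @export
#' @examples
#' label_map(0)
#' label_map("S_Drinking")
label_map <- function(code_or_name) {
  tab <- activity_labels()
  if (is.numeric(code_or_name)) {
    if (length(code_or_name) != 1L || is.na(code_or_name) ||
        code_or_name != as.integer(code_or_name) ||
        !(code_or_name %in% tab$code)) {
      stop("unknown activity code: ", code_or_name, call. = FALSE)
    }
    row <- tab[tab$code == as.integer(code_or_name), ]
  } else if (is.character(code_or_name)) {
    if (length(code_or_name) != 1L || !(code_or_name %in% tab$name)) {
      stop("unknown activity name: ", code_or_name, call. = FALSE)
    }
    row <- tab[tab$name == code_or_name, ]
  } else {
    stop("label must be an integer code or a character name", call. = FALSE)
  }
  structure(
    list(code = row$code, name = row$name, type_group = row$type_group,
         is_primary = row$is_primary),
    class = "activity_label"
  )
}

#' @export
print.activity_label <- function(x, ...) {
  cat(sprintf("<activity %d: %s [%s, %s]>\n", x$code, x$name, x$type_group,
              if (x$is_primary) "primary" else "secondary"))
  invisible(x)
}
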