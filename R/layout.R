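#' Circuit layout of an MEA
#'
#' A circuit layout maps electrode ids to circuits of four electrodes
#' arranged on a ring. Positions are numbered clockwise: 1 top-left,
#' 2 top-right, 3 bottom-right, 4 bottom-left, so the clockwise direction
#' is 1 -> 2 -> 3 -> 4 -> 1. Adjacent position pairs are (1,2), (2,3),
#' (3,4), (4,1); diagonal pairs are (1,3) and (2,4).
#'
#' @param electrode integer vector of electrode ids.
#' @param circuit integer vector, circuit id of each electrode.
#' @param position integer vector in 1..4, clockwise position of each
#'   electrode within its circuit.
#' @return An object of class `circuit_layout`: a data frame with columns
#'   `electrode`, `circuit`, `position`.
#' @examples
#' lay <- default_layout()
#' nrow(lay)            # 60 electrodes
#' length(unique(lay$circuit))  # 15 circuits
#' @export
circuit_layout <- function(electrode, circuit, position) {
  lay <- data.frame(electrode = as.integer(electrode),
                    circuit = as.integer(circuit),
                    position = as.integer(position))
  validate_layout(lay)
  lay <- lay[order(lay$circuit, lay$position), , drop = FALSE]
  rownames(lay) <- NULL
  class(lay) <- c("circuit_layout", "data.frame")
  lay
}

validate_layout <- function(lay) {
  if (anyNA(lay)) stop("layout contains missing values")
  if (anyDuplicated(lay$electrode))
    stop("electrode listed in more than one circuit (or twice): ",
         paste(unique(lay$electrode[duplicated(lay$electrode)]), collapse = ", "))
  if (!all(lay$position %in% 1:4))
    stop("positions must be in 1..4")
  split_pos <- split(lay$position, lay$circuit)
  bad <- names(split_pos)[!vapply(split_pos, function(p)
    length(p) == 4L && setequal(p, 1:4), logical(1))]
  if (length(bad))
    stop("each circuit needs exactly 4 electrodes, one per position; bad circuit(s): ",
         paste(bad, collapse = ", "))
  invisible(lay)
}

#' Default 60-electrode layout: 15 circuits of 4 electrodes
#'
#' Electrodes 1..60 are assigned consecutively, circuit `c` holding
#' electrodes `4(c-1)+1 .. 4c` at positions 1..4.
#' @return A `circuit_layout` with 15 circuits and 60 electrodes.
#' @export
default_layout <- function() {
  circuit_layout(electrode = 1:60,
                 circuit = rep(1:15, each = 4L),
                 position = rep(1:4, times = 15L))
}

#' Read a circuit layout from JSON
#'
#' Expected shape: `{"circuits":[{"id":1,"electrodes":{"1":id,...,"4":id}}]}`.
#' @param path path to a layout JSON file.
#' @return A validated `circuit_layout`.
#' @export
load_layout <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (is.null(obj$circuits)) stop("layout JSON lacks a 'circuits' field: ", path)
  rows <- lapply(obj$circuits, function(circ) {
    el <- circ$electrodes
    if (length(el) != 4L)
      stop("circuit ", circ$id, " has ", length(el), " electrodes, expected 4")
    pos <- as.integer(names(el))
    data.frame(electrode = as.integer(unlist(el, use.names = FALSE)),
               circuit = as.integer(circ$id), position = pos)
  })
  lay <- do.call(rbind, rows)
  circuit_layout(lay$electrode, lay$circuit, lay$position)
}

#' Write a circuit layout to JSON
#' @param layout a `circuit_layout`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_layout <- function(layout, path) {
  circs <- lapply(split(layout, layout$circuit), function(d) {
    d <- d[order(d$position), ]
    list(id = d$circuit[1],
         electrodes = stats::setNames(as.list(d$electrode), as.character(d$position)))
  })
  jsonlite::write_json(list(circuits = unname(circs)), path,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Look up circuit / position of electrodes
#' @param layout a `circuit_layout`.
#' @param electrode electrode id(s).
#' @return integer vector (NA for electrodes outside any circuit).
#' @export
circuit_of <- function(layout, electrode) {
  layout$circuit[match(electrode, layout$electrode)]
}

#' @rdname circuit_of
#' @export
position_of <- function(layout, electrode) {
  layout$position[match(electrode, layout$electrode)]
}

#' Electrodes of one circuit, in clockwise position order
#' @param layout a `circuit_layout`.
#' @param circuit circuit id.
#' @return integer vector of 4 electrode ids (positions 1..4).
#' @export
circuit_electrodes <- function(layout, circuit) {
  d <- layout[layout$circuit == circuit, ]
  if (!nrow(d)) stop("no such circuit: ", circuit)
  d$electrode[order(d$position)]
}

# clockwise neighbour of a position on the ring
cw_position <- function(pos) pos %% 4L + 1L
ccw_position <- function(pos) (pos - 2L) %% 4L + 1L
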