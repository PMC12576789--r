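# Curated transcription of the denticles_v0.5 character scheme: 46 traits in
# groups A-O, each with its printed disparity weight, enumerated states, and a
# state-distance matrix built from the trait's verbal disparity description via
# build_matrix_from_descriptors(). The bundled JSON asset is generated from
# this table and frozen; a test asserts the two stay identical.

# zero_meaning shorthands
.BROKEN <- "broken/unobservable"
.NOTAPP <- "not-applicable"
.NESTED <- "absent-nested"

v05_trait_table <- function() {
  t <- list()
  def <- function(id, group, name, weight, labels, first, zero_label = NULL,
                  zero_meaning = NA_character_, mat) {
    idx <- seq(first, length.out = length(labels))
    st <- data.frame(index = idx, label = labels, stringsAsFactors = FALSE)
    if (!is.null(zero_label))
      st <- rbind(data.frame(index = 0L, label = zero_label,
                             stringsAsFactors = FALSE), st)
    t[[id]] <<- trait_def(id, group, name, weight, st, mat, zero_meaning)
  }
  # convenience matrix builders over non-zero states `s`
  flat <- function(s, word = "different")
    build_matrix_from_descriptors(s, pairs_default(s, word))
  ordinal <- function(s) {
    p <- data.frame(a = s[-length(s)], b = s[-1], descriptor = "step")
    build_matrix_from_descriptors(s, p, complete = "path")
  }

  ## -- A: general crown shape ------------------------------------------------
  p <- pairs_default(1:9)
  p <- pairs_set(p, 2, 3, "very different")      # cruciform vs rounder shapes
  p <- pairs_set(p, 3, c(5, 9), "very different") # circular vs angular shapes
  p <- pairs_set(p, 1, 2:9, "maximal")            # spines vs everything
  def("A1", "A", "Overall crown shape", 2,
      c("Spine", "Cruciform", "Circular/Oval", "Spade", "Diamond/Rectangle",
        "Elongated Asymmetrical", "Irregular/Other", "Fan-like",
        "Triangular/Arrow-like"), 1,
      mat = build_matrix_from_descriptors(1:9, p))

  p <- pairs_default(1:6)
  p <- pairs_set(p, 1, 5, "similar")  # lobed ~ rounded (both rounded edges)
  p <- pairs_set(p, 3, 4, "similar")  # pointed ~ stretched (pointed posterior)
  def("A2", "A", "Spade subtype", 0.5,
      c("Rounded", "Squared", "Pointed", "Stretched", "Lobed", "Irregular"),
      1, "Not a spade", .NOTAPP, build_matrix_from_descriptors(1:6, p))

  ## -- B/C: anterior and posterior characteristics ---------------------------
  bc_shape <- function() {
    p <- pairs_default(1:4, "similar")       # one step between coded shapes
    p <- pairs_set(p, 4, 1:3, "very different") # no-directionality stands out
    build_matrix_from_descriptors(1:4, p)
  }
  bc_macro <- function() {
    p <- pairs_default(1:4)
    p <- pairs_set(p, 1, c(2, 3), "significantly different") # vs smooth
    build_matrix_from_descriptors(1:4, p)
  }
  def("B1", "B", "Anterior shape", 1,
      c("Straight", "Rounded", "Pointed", "No directionality"), 1,
      "Anterior too broken to code", .BROKEN, bc_shape())
  def("B2", "B", "Anterior macro texture", 1,
      c("Smooth", "Scalloped", "Pointed", "Vertex"), 1,
      "Anterior too broken to code", .BROKEN, bc_macro())
  def("B3", "B", "Anterior micro texture", 1,
      c("Smooth", "Serrated"), 1, mat = flat(1:2, "equally different"))
  def("C1", "C", "Posterior shape", 1,
      c("Straight", "Rounded", "Pointed", "No directionality"), 1,
      "Posterior too broken to code", .BROKEN, bc_shape())
  def("C2", "C", "Posterior macro texture", 1,
      c("Smooth", "Scalloped", "Pointed", "Vertex"), 1,
      "Posterior too broken to code", .BROKEN, bc_macro())
  def("C3", "C", "Posterior micro texture", 1,
      c("Smooth", "Serrated"), 1, mat = flat(1:2, "equally different"))

  ## -- D: symmetry -----------------------------------------------------------
  p <- pairs_default(1:4, "very different")
  p <- pairs_set(p, 2, 3, "similar")   # one vs two planes: least different
  p <- pairs_set(p, 1, 4, "maximal")   # asymmetric vs radial: farthest
  def("D1", "D", "Planes of symmetry", 1,
      c("None/Asymmetrical", "One", "Two", "Three+/Radial"), 1,
      mat = build_matrix_from_descriptors(1:4, p))

  ## -- E: cusps --------------------------------------------------------------
  # cusped states differ in unit steps; no-cusps row is flat
  p <- data.frame(a = 2:10, b = 3:11, descriptor = "step")
  p <- rbind(p, data.frame(a = 1, b = 2:11, descriptor = "very different"))
  def("E1", "E", "Number of cusps", 1,
      c("No cusps", "One cusp", "Two cusps", "Three cusps", "Four cusps",
        "Five cusps", "Six cusps", "Seven cusps", "Eight cusps", "Nine cusps",
        "Ten or more cusps"), 1,
      mat = build_matrix_from_descriptors(1:11, p, complete = "path"))
  def("E2", "E", "Cusp-ridge association", 0.5,
      c("Not associated", "Associated", "Some associated"), 1,
      "No cusps", .NESTED, flat(1:3, "somewhat different"))
  p <- pairs_default(1:4, "somewhat different")
  p <- pairs_set(p, 4, 1:3, "very different")  # irregular cusps stand out
  def("E3", "E", "Cusp similarity", 0.5,
      c("Similar", "Central distinct", "Opposite similar", "Irregular"), 1,
      "No cusps/only one cusp", .NESTED,
      build_matrix_from_descriptors(1:4, p))
  def("E4", "E", "Relative cusp length", 0.5,
      c("< 1/4 crown", "1/4 - 1/2 crown", "> 1/2 crown"), 1,
      "No cusps", .NESTED, ordinal(1:3))

  ## -- F-H: overall ridge characteristics ------------------------------------
  p <- pairs_default(1:6)
  irr <- c(3, 4, 6)                       # geometric, meandering, branching
  p <- pairs_set(p, irr, irr, "similar")  # irregular ridge systems cluster
  p <- pairs_set(p, 2, 5, "different")    # linear vs spine
  p <- pairs_set(p, c(2, 5), irr, "very different")
  p <- pairs_set(p, 1, 2:6, "maximal")    # smooth: the only no-ridge system
  def("F1", "F", "Ridge system", 2,
      c("Smooth", "Linear", "Geometric", "Meandering", "Spine", "Branching"),
      1, mat = build_matrix_from_descriptors(1:6, p))

  p <- data.frame(a = 2:7, b = 3:8, descriptor = "step")
  p <- rbind(p, data.frame(a = 1, b = 2:8, descriptor = "very different"))
  def("G1", "G", "Number of ridge segments", 1,
      c("None", "One", "Two", "Three", "Four", "Five", "Six-ten",
        "Eleven or more"), 1,
      mat = build_matrix_from_descriptors(1:8, p, complete = "path"))

  p <- pairs_default(1:7)
  p <- pairs_set(p, 3:6, 3:6, "similar")  # two..five: equally dissimilar
  p <- pairs_set(p, 1, 2:7, "very different")
  def("G2", "G", "Number of independent ridges", 1,
      c("None", "One", "Two", "Three", "Four", "Five", "Six or more"), 1,
      mat = build_matrix_from_descriptors(1:7, p))

  p <- pairs_default(1:3)
  p <- pairs_set(p, 2, 3, "similar")  # one vs two outgrowths: least different
  def("G3", "G", "Ridge outgrowths", 1,
      c("No outgrowths", "One outgrowth", "Two outgrowths"), 1,
      "No ridges or broken", .NESTED, build_matrix_from_descriptors(1:3, p))

  p <- pairs_default(1:8)
  p <- pairs_set(p, 1:3, 1:3, "similar")  # parallel/converge/diverge cluster
  p <- pairs_set(p, 5, 6, "similar")      # intersect ~ apex-radial
  p <- pairs_set(p, c(5, 6), 1:4, "very different")
  def("H1", "H", "Ridge orientation", 0.5,
      c("Parallel", "Converging", "Diverging", "Diverge-converge",
        "Intersect/branch", "Apex radial", "Irregular", "Multiple"), 1,
      "Only one ridge/no ridges", .NESTED,
      build_matrix_from_descriptors(1:8, p))

  ## -- I/J: central and non-central ridges -----------------------------------
  p <- pairs_default(1:4, "very different")
  p <- pairs_set(p, 1, 2, "similar")      # no-central ~ only-one
  p <- pairs_set(p, 2, c(3, 4), "similar") # only-one ~ central-ridged
  p <- pairs_set(p, 3, 4, "different")    # same vs distinct central ridge
  def("I1", "I", "Central ridge disparity", 0.5,
      c("No central ridge", "Only one ridge", "Same as other ridges",
        "Distinct from other ridges"), 1, "No ridges", .NESTED,
      build_matrix_from_descriptors(1:4, p))

  p <- pairs_default(1:3)
  p <- pairs_set(p, 1, 2, "similar")  # straight ~ curved
  def("I2", "I", "Central ridge directionality", 0.5,
      c("Straight", "Curved", "Meandering"), 1,
      "No central ridge", .NESTED, build_matrix_from_descriptors(1:3, p))

  ij_width <- function(s) {
    p <- pairs_default(s)
    p <- pairs_set(p, 1, utils::tail(s, 2), "most dissimilar") # troughs/irreg
    build_matrix_from_descriptors(s, p)
  }
  def("I3", "I", "Central ridge width", 0.5,
      c("Parallel", "Widening", "Thinning", "Diamond-like", "Central trough",
        "Irregular"), 1, "No central ridge", .NESTED, ij_width(1:6))

  p <- pairs_default(1:5)
  p <- pairs_set(p, 2, 3, "similar")  # concave ~ convex
  p <- pairs_set(p, c(4, 5), 1:3, "most dissimilar")
  p <- pairs_set(p, 4, 5, "similar")  # meandering ~ combination
  def("J1", "J", "Non-central ridge directionality", 0.5,
      c("Straight", "Concave curved", "Convex curved", "Meandering",
        "Combination"), 1, "None/only central ridge", .NESTED,
      build_matrix_from_descriptors(1:5, p))
  def("J2", "J", "Non-central ridge width", 0.5,
      c("Parallel", "Widening", "Thinning", "Diamond-like", "Troughs",
        "Irregular/Combination"), 1, "None/only central ridge", .NESTED,
      ij_width(1:6))

  ## -- K: central ridge system ------------------------------------------------
  geo <- c(2:7, 9)  # enclosed geometric central shapes share a dimple
  p <- pairs_default(1:11)
  p <- pairs_set(p, geo, geo, "similar")
  p <- pairs_set(p, 1, 2:11, "very different")  # shape vs no shape
  p <- pairs_set(p, 8, setdiff(1:11, 8), "very different")  # mound
  p <- pairs_set(p, 11, 8, "different")
  p <- pairs_set(p, 10, setdiff(1:11, 10), "very different") # multiple shapes
  def("K1", "K", "Central ridge system shape", 1,
      c("No central shape", "Circular/Oval", "Triangular", "Quadrilateral",
        "Pentagonal", "Hexagonal", "Heptagonal", "Mound", "Octagonal",
        "Multiple", "Irregular"), 1, "No ridges", .NESTED,
      build_matrix_from_descriptors(1:11, p))

  p <- pairs_default(1:4)
  p <- pairs_set(p, 1, c(2, 3), "very different")
  p <- pairs_set(p, 1, 4, "maximal")  # no symmetry vs radial
  p <- pairs_set(p, 2, 3, "similar")
  def("K2", "K", "Central shape symmetry", 0.5,
      c("No symmetry", "One", "Two", "Radial"), 1,
      "No central ridge system shape", .NESTED,
      build_matrix_from_descriptors(1:4, p))

  ## -- L: ridge size ----------------------------------------------------------
  p <- pairs_default(1:5, "very different")
  p <- pairs_set(p, 2:4, 2:4, "similar")  # the three plain length classes
  def("L1", "L", "Ridge length", 0.5,
      c("No ridges", "Edge to edge", "Begins or ends mid-crown",
        "Begins and ends mid-crown", "Combination"), 1,
      mat = build_matrix_from_descriptors(1:5, p))

  p <- pairs_default(1:4)
  p <- pairs_set(p, 1, c(2, 4), "very different")
  p <- pairs_set(p, 1, 3, "maximal")  # undefined vs fully defined
  p <- pairs_set(p, 2, 4, "similar")  # partly defined ~ central-only
  def("L2", "L", "Ridge definition", 0.5,
      c("Not clearly defined", "Partially defined", "Clearly defined",
        "Central ridge only"), 1, "No ridges", .NESTED,
      build_matrix_from_descriptors(1:4, p))

  p <- pairs_default(1:3)
  p <- pairs_set(p, 1, c(2, 3), "very different")  # one ridge vs multiple
  def("L3", "L", "Relative ridge heights", 0.5,
      c("Only one ridge", "Equal", "Variable"), 1, "No ridges", .NESTED,
      build_matrix_from_descriptors(1:3, p))

  p <- pairs_default(1:5)
  p <- pairs_set(p, 4, setdiff(1:5, 4), "very different")  # variable profiles
  def("L4", "L", "Ridge/trough angularity", 0.5,
      c("Rounded", "Triangular", "Funnel", "Variable/other", "Rectangular"),
      1, "No ridges", .NESTED, build_matrix_from_descriptors(1:5, p))

  ## -- M: depressions and dimples ---------------------------------------------
  p <- data.frame(a = 2:5, b = 3:6, descriptor = "step")
  p <- rbind(p,
             data.frame(a = 1, b = 2:7, descriptor = "very different"),
             data.frame(a = 7, b = 3, descriptor = "similar"),
             # "multiple, number unknown" sits at the level of 'two'
             data.frame(a = 7, b = c(2, 4), descriptor = "step"),
             data.frame(a = 7, b = 5, descriptor = "different"),
             data.frame(a = 7, b = 6, descriptor = "very different"))
  def("M1", "M", "Number of depressions", 1,
      c("None", "One", "Two", "Three", "Four", "Five or more",
        "Multiple (broken)"), 1,
      mat = build_matrix_from_descriptors(1:7, p, complete = "path"))
  def("M2", "M", "Depression type", 0.5,
      c("Thumbprint", "Open tunnel", "Dimples"), 1,
      "No depression", .NESTED, flat(1:3, "equally different"))
  p <- pairs_default(1:3, "very different")
  p <- pairs_set(p, 1, 2, "similar")  # central ~ edge; both-vs-single stands
  def("M3", "M", "Depression location", 0.5,
      c("Central", "Edge", "Central and edge"), 1,
      "No depression", .NESTED, build_matrix_from_descriptors(1:3, p))
  def("M4", "M", "Dimple shape", 0.5,
      c("Circle", "Elongated", "Teardrop", "Quadrilateral", "Pentagon",
        "Irregular", "Multiple shapes"), 1,
      "No dimples", .NESTED, flat(1:7, "equally different"))

  ## -- N: secondary features and surface textures ------------------------------
  p <- pairs_default(1:7)
  p <- pairs_set(p, 4:6, 4:6, "similar")  # the surface textures cluster
  p <- pairs_set(p, 3, 4:6, "similar")    # micro-reliefs: least distinct
  p <- pairs_set(p, 1, 2:7, "very different")
  p <- pairs_set(p, 7, setdiff(1:7, 7), "very different")  # protrusions
  def("N1", "N", "Secondary ridge features", 1,
      c("No ridges", "No secondary features", "Micro-reliefs", "Honeycomb",
        "Wavy", "Honeycomb/wavy", "Vertical protrusions"), 1,
      mat = build_matrix_from_descriptors(1:7, p))
  p <- pairs_default(1:7)
  p <- pairs_set(p, 1, 3, "very different")  # ridges-only vs crown-except
  p <- pairs_set(p, 2, 4:7, "very different") # whole crown vs local patches
  def("N2", "N", "Surface texture location", 0.5,
      c("Ridges only", "Crown and ridges", "Crown except ridges", "Anterior",
        "Middle", "Posterior", "Edges"), 1,
      "No secondary features", .NESTED, build_matrix_from_descriptors(1:7, p))
  def("N3", "N", "Surface texture coverage", 0.5,
      c("< 30%", "30 - 70%", "> 70%"), 1,
      "No surface texture", .NESTED, ordinal(1:3))

  ## -- O: base characteristics -------------------------------------------------
  .O0 <- "Base not preserved/not observable"
  p <- pairs_default(1:12)
  p <- pairs_set(p, 11, setdiff(1:12, 11), "very different") # mirrors crown
  p <- pairs_set(p, 10, setdiff(1:12, 10), "maximal")        # tree roots
  p <- pairs_set(p, 12, setdiff(1:12, 12), "maximal")        # no separation
  def("O1", "O", "Base shape", 1,
      c("Kite", "Kite/cruciform extended", "Kite/cruciform partial",
        "Rhombus", "Rounded rhombus", "Stretched rhombus",
        "Trapezoid/rhombus", "Oval", "Circular", "Tree roots",
        "Mirrors crown", "Extends from crown"), 1, .O0, .BROKEN,
      build_matrix_from_descriptors(1:12, p))
  p <- pairs_default(1:4)
  p <- pairs_set(p, 4, 1:3, "very different")  # no directionality
  def("O2", "O", "Base width/length", 1,
      c("Equal", "Wider than long", "Longer than wide", "No directionality"),
      1, .O0, .BROKEN, build_matrix_from_descriptors(1:4, p))
  def("O3", "O", "Crown to base ratio", 1,
      c("Equal area", "Crown larger", "Base larger"), 1, .O0, .BROKEN,
      flat(1:3, "equally different"))
  p <- pairs_default(1:7)
  p <- pairs_set(p, 1, 2:7, "very different")  # no grooves vs grooved
  def("O4", "O", "Number of grooves", 1,
      c("No grooves", "One", "Two", "Three", "Four", "Five", "Six or more"),
      1, .O0, .BROKEN, build_matrix_from_descriptors(1:7, p))
  p <- pairs_default(1:5)
  p <- pairs_set(p, 1, 2:5, "very different")  # no opening vs any shape
  def("O5", "O", "Root foramen shape", 1,
      c("No root opening", "Rhombus", "Ellipse", "Arc", "Mirrors base"), 1,
      .O0, .BROKEN, build_matrix_from_descriptors(1:5, p))
  def("O6", "O", "Root foramen location", 1,
      c("Center", "Anterior", "Posterior"), 1,
      "Not preserved or no root opening", .BROKEN,
      flat(1:3, "equally different"))
  p <- pairs_default(1:4)
  p <- pairs_set(p, 4, 1:3, "very different")  # no peduncle
  def("O7", "O", "Peduncle height:width", 1,
      c("Equal", "Wider than high", "Higher than wide", "No peduncle"), 1,
      .O0, .BROKEN, build_matrix_from_descriptors(1:4, p))
  def("O8", "O", "Crown to root angle", 1,
      c("Perpendicular", "Obtuse", "Parallel", "Acute"), 1, .O0, .BROKEN,
      ordinal(1:4))  # semi-continuous: perpendicular-obtuse-parallel-acute
  def("O9", "O", "Base connection location", 1,
      c("Anterior", "Center", "Posterior"), 1, .O0, .BROKEN,
      flat(1:3, "equally different"))
  def("O10", "O", "Mound", 1,
      c("Not mounded", "Mounded"), 1, .O0, .BROKEN,
      flat(1:2, "different"))

  t
}

v05_nesting_rules <- function() {
  rule <- function(controller, when, ...) {
    req <- list(...)
    list(controller = controller, when = as.integer(when),
         requires = lapply(req, as.integer))
  }
  list(
    # A2 describes spade sub-shape only when A1 is a spade (state 4)
    rule("A1", c(1:3, 5:9), A2 = 0),
    # cusp descriptors require cusps
    rule("E1", 1, E2 = 0, E3 = 0, E4 = 0),
    rule("E1", 2, E3 = 0),  # similarity needs more than one cusp
    # a smooth crown has no ridge characters at all
    rule("F1", 1,
         G1 = 1, G2 = 1, G3 = 0, H1 = 0,
         I1 = 0, I2 = 0, I3 = 0, J1 = 0, J2 = 0,
         K1 = 0, K2 = 0,
         L1 = 1, L2 = 0, L3 = 0, L4 = 0,
         N1 = 1, N2 = 0, N3 = 0),
    # central-ridge descriptors require a central ridge
    rule("I1", 1, I2 = 0, I3 = 0),
    # central-shape symmetry requires an observed central shape
    rule("K1", c(0, 1), K2 = 0),
    # depression descriptors require depressions; dimple shape requires dimples
    rule("M1", 1, M2 = 0, M3 = 0, M4 = 0),
    rule("M2", c(1, 2), M4 = 0),
    # surface-texture location/coverage require a surface texture (N1 4-6)
    rule("N1", c(1, 2, 3, 7), N2 = 0, N3 = 0),
    # foramen location requires a foramen
    rule("O5", c(0, 1), O6 = 0)
  )
}

#' Qualitative ordering checks for the shipped distance matrices
#'
#' The trait disparity descriptions are verbal orderings ("more similar",
#' "very different from all other", "one step increments"). This function
#' evaluates those orderings, transcribed as explicit comparisons, against a
#' schema's distance matrices. Only orderings are asserted — the shipped
#' numeric values are one faithful monotone realization, and externally
#' supplied matrices are checked on the same terms.
#'
#' @param schema A `denticle_schema` (defaults to the bundled v0.5).
#' @return Data frame with columns `check` (description) and `ok`.
#' @export
#' @examples
#' all(matrix_ordering_checks()$ok)
matrix_ordering_checks <- function(schema = load_schema("denticles_v0.5")) {
  d <- function(id, a, b) trait_distance(schema, id, a, b)
  checks <- list(
    "A1: spine farther from diamond than diamond from triangle" =
      d("A1", 1, 5) > d("A1", 5, 9),
    "A1: spine equally very different from all other shapes" =
      d("A1", 1, 2) == d("A1", 1, 9),
    "A1: circular farther from angular diamond than diamond from triangle" =
      d("A1", 3, 5) > d("A1", 5, 9),
    "A2: lobed spade closer to rounded than squared is" =
      d("A2", 1, 5) < d("A2", 1, 2),
    "A2: pointed closer to stretched than to rounded" =
      d("A2", 3, 4) < d("A2", 1, 3),
    "B1: lacking directionality stands apart from coded shapes" =
      d("B1", 1, 4) > d("B1", 1, 2),
    "B1: coded anterior shapes differ by equal single steps" =
      d("B1", 1, 2) == d("B1", 2, 3),
    "B2: smooth farther from scalloped than scalloped from pointed" =
      d("B2", 1, 2) > d("B2", 2, 3),
    "B2: scalloped and pointed equally far from smooth" =
      d("B2", 1, 2) == d("B2", 1, 3),
    "B3: the two micro textures are equally different" =
      d("B3", 1, 2) == 2,
    "C1: lacking directionality stands apart from coded shapes" =
      d("C1", 1, 4) > d("C1", 1, 2),
    "C2: smooth farther from scalloped than scalloped from pointed" =
      d("C2", 1, 2) > d("C2", 2, 3),
    "D1: radial farthest from asymmetric" =
      d("D1", 1, 4) > d("D1", 2, 3),
    "D1: asymmetric significantly different from one plane" =
      d("D1", 1, 2) > d("D1", 2, 3),
    "D1: radial equally far from one and two planes" =
      d("D1", 2, 4) == d("D1", 3, 4),
    "E1: cusp counts differ in unit steps" =
      d("E1", 2, 3) == d("E1", 3, 4),
    "E1: two-step cusp difference is twice one step" =
      d("E1", 2, 4) == 2 * d("E1", 2, 3),
    "E1: no-cusps equally far from any cusped state" =
      d("E1", 1, 2) == d("E1", 1, 6),
    "E4: length bins are ordinal unit steps" =
      d("E4", 1, 3) == 2 * d("E4", 1, 2),
    "F1: geometric closer to meandering than to smooth" =
      d("F1", 3, 4) < d("F1", 3, 1),
    "F1: branching closer to geometric than linear is" =
      d("F1", 3, 6) < d("F1", 3, 2),
    "F1: spine closer to linear than to geometric" =
      d("F1", 2, 5) < d("F1", 2, 3),
    "F1: smooth maximally distinct from every ridge system" =
      d("F1", 1, 2) == max(schema$traits$F1$dist),
    "G1: segment counts differ in unit steps" =
      d("G1", 2, 3) == d("G1", 3, 4),
    "G2: counted independent ridges equally dissimilar" =
      d("G2", 3, 4) == d("G2", 4, 5),
    "G2: none farther from two ridges than two from three" =
      d("G2", 1, 3) > d("G2", 3, 4),
    "G3: one and two outgrowths less dissimilar than none vs one" =
      d("G3", 2, 3) < d("G3", 1, 2),
    "H1: parallel closer to converging than to intersecting" =
      d("H1", 1, 2) < d("H1", 1, 5),
    "H1: apex-radial closer to intersecting than to diverge-converge" =
      d("H1", 5, 6) < d("H1", 4, 5),
    "I1: no-central closer to only-one than to same-as-others" =
      d("I1", 1, 2) < d("I1", 1, 3),
    "I2: straight closer to curved than to meandering" =
      d("I2", 1, 2) < d("I2", 1, 3),
    "I3: central trough most dissimilar from parallel" =
      d("I3", 1, 5) > d("I3", 1, 2),
    "J1: the two curvatures closer to each other than to straight" =
      d("J1", 2, 3) < d("J1", 1, 2),
    "J1: meandering closer to combination than to straight" =
      d("J1", 4, 5) < d("J1", 1, 4),
    "K1: circular central shape closer to triangular than to mound" =
      d("K1", 2, 3) < d("K1", 2, 8),
    "K1: central shape very different from no central shape" =
      d("K1", 1, 2) > d("K1", 2, 3),
    "K2: central-shape radial farthest from no-symmetry" =
      d("K2", 1, 4) > d("K2", 2, 4),
    "K2: one and two planes least different" =
      d("K2", 2, 3) < d("K2", 2, 4),
    "L1: plain length classes closer than to combination" =
      d("L1", 2, 3) < d("L1", 2, 5),
    "L2: undefined ridges farthest from clearly defined" =
      d("L2", 1, 3) > d("L2", 1, 2),
    "L2: partial definition closer to central-only than to clear" =
      d("L2", 2, 4) < d("L2", 3, 4),
    "L3: single ridge very different from multiple" =
      d("L3", 1, 2) > d("L3", 2, 3),
    "L4: variable profile most different" =
      d("L4", 1, 4) > d("L4", 1, 2),
    "M1: depression counts differ in unit steps" =
      d("M1", 2, 3) == d("M1", 3, 4),
    "M1: uncounted-multiple sits at the level of two depressions" =
      d("M1", 7, 5) == d("M1", 3, 5),
    "M3: central and edge closer than either to both" =
      d("M3", 1, 2) < d("M3", 1, 3),
    "N1: surface textures cluster together" =
      d("N1", 4, 5) < d("N1", 2, 4),
    "N1: protrusions most different from textures" =
      d("N1", 7, 4) > d("N1", 4, 5),
    "N2: ridges-only farthest from crown-except-ridges" =
      d("N2", 1, 3) > d("N2", 1, 4),
    "N2: whole crown farther from local patches" =
      d("N2", 2, 4) > d("N2", 4, 5),
    "N3: coverage bins are ordinal unit steps" =
      d("N3", 1, 3) == 2 * d("N3", 1, 2),
    "O1: tree roots very different from all other base shapes" =
      d("O1", 10, 1) > d("O1", 1, 4),
    "O1: mirrors-crown stands apart, but less than tree roots" =
      d("O1", 11, 1) > d("O1", 1, 4) && d("O1", 11, 1) < d("O1", 10, 1),
    "O2: no-directionality stands apart" =
      d("O2", 4, 1) > d("O2", 1, 2),
    "O4: no grooves farther from grooved than grooved among themselves" =
      d("O4", 1, 2) > d("O4", 2, 3),
    "O5: no opening farther from any foramen shape" =
      d("O5", 1, 2) > d("O5", 2, 3),
    "O7: no peduncle stands apart" =
      d("O7", 4, 1) > d("O7", 1, 2),
    "O8: crown-to-root angle is semi-continuous" =
      d("O8", 1, 4) > d("O8", 1, 2) && d("O8", 1, 2) == d("O8", 2, 3)
  )
  data.frame(check = names(checks), ok = unlist(checks, use.names = FALSE),
             stringsAsFactors = FALSE)
}

#' Construct the denticles_v0.5 schema from the curated descriptor tables
#'
#' This is the generator behind the bundled `denticles_v0.5.json` asset; the
#' asset is frozen and the two are asserted identical in the test suite.
#' Prefer [load_schema()] for ordinary use.
#'
#' @return A validated `denticle_schema` with 46 traits.
#' @export
build_v05_schema <- function() {
  sch <- new_schema("denticles_v0.5", v05_trait_table(), v05_nesting_rules())
  issues <- validate_schema(sch)
  if (nrow(issues) > 0)
    stop("internal error: curated v0.5 schema invalid: ",
         paste(issues$message, collapse = "; "))
  sch
}
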