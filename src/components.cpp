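#include <Rcpp.h>
#include <vector>
using namespace Rcpp;

// Connected-component labeling of a binary mask by breadth-first flood
// fill. Labels are assigned in raster order (top-to-bottom, then
// left-to-right), so label 1 is the component containing the first
// foreground pixel met when scanning rows. connectivity is 4 or 8.
// [[Rcpp::export]]
IntegerMatrix cc_label_cpp(LogicalMatrix mask, int connectivity) {
  const int H = mask.nrow(), W = mask.ncol();
  IntegerMatrix lab(H, W);
  if (connectivity != 4 && connectivity != 8)
    stop("connectivity must be 4 or 8");
  const int dx8[8] = {1, -1, 0, 0, 1, 1, -1, -1};
  const int dy8[8] = {0, 0, 1, -1, 1, -1, 1, -1};
  const int nnb = (connectivity == 4) ? 4 : 8;
  int next = 0;
  std::vector<int> stack;
  stack.reserve(1024);
  for (int y = 0; y < H; ++y) {
    for (int x = 0; x < W; ++x) {
      if (!mask(y, x) || lab(y, x) != 0) continue;
      ++next;
      lab(y, x) = next;
      stack.push_back(y + x * H);
      while (!stack.empty()) {
        int idx = stack.back();
        stack.pop_back();
        int cy = idx % H, cx = idx / H;
        for (int k = 0; k < nnb; ++k) {
          int nx = cx + dx8[k], ny = cy + dy8[k];
          if (nx < 0 || nx >= W || ny < 0 || ny >= H) continue;
          if (mask(ny, nx) && lab(ny, nx) == 0) {
            lab(ny, nx) = next;
            stack.push_back(ny + nx * H);
          }
        }
      }
    }
  }
  return lab;
}

// Moore-neighbour boundary tracing of the (single) 8-connected object in
// `mask`. Returns the polygonal length of the traced outer contour, with
// axis steps counting 1 and diagonal steps sqrt(2), plus the contour
// vertices (0-based x,y). Objects of one pixel have length 0; a pair of
// pixels traces there-and-back (length 2 or 2*sqrt(2)).
// [[Rcpp::export]]
List trace_contour_cpp(LogicalMatrix mask) {
  const int H = mask.nrow(), W = mask.ncol();
  // clockwise with y pointing down: E, SE, S, SW, W, NW, N, NE
  const int dx[8] = {1, 1, 0, -1, -1, -1, 0, 1};
  const int dy[8] = {0, 1, 1, 1, 0, -1, -1, -1};
  int sx = -1, sy = -1;
  for (int y = 0; y < H && sx < 0; ++y)
    for (int x = 0; x < W; ++x)
      if (mask(y, x)) { sx = x; sy = y; break; }
  if (sx < 0) return List::create(_["perimeter"] = 0.0,
                                  _["x"] = IntegerVector(0),
                                  _["y"] = IntegerVector(0));
  std::vector<int> cxs, cys;
  cxs.push_back(sx); cys.push_back(sy);
  double per = 0.0;
  // backtrack position: we "came from" the west of the start pixel
  // (guaranteed background because the start is the topmost-leftmost
  // foreground pixel)
  int cx = sx, cy = sy, bx = sx - 1, by = sy;
  int first_move = -1;
  long guard = 0, maxit = 10L * H * W + 64;
  while (true) {
    // direction from current pixel to its backtrack cell
    int dirb = -1;
    for (int d = 0; d < 8; ++d)
      if (cx + dx[d] == bx && cy + dy[d] == by) { dirb = d; break; }
    int found = -1, px = 0, py = 0, lbx = bx, lby = by;
    for (int k = 1; k <= 8; ++k) {
      int d = (dirb + k) % 8;
      int nx = cx + dx[d], ny = cy + dy[d];
      bool fg = nx >= 0 && nx < W && ny >= 0 && ny < H && mask(ny, nx);
      if (fg) { found = d; px = nx; py = ny; break; }
      lbx = nx; lby = ny;
    }
    if (found < 0) break;  // isolated pixel
    // stop when, back at the start pixel, the trace is about to repeat
    // its very first move (the contour is closed)
    if (first_move < 0) first_move = found;
    else if (cx == sx && cy == sy && found == first_move) break;
    per += (found % 2 == 0) ? 1.0 : M_SQRT2;
    cx = px; cy = py; bx = lbx; by = lby;
    cxs.push_back(cx); cys.push_back(cy);
    if (++guard > maxit) stop("contour tracing did not terminate");
  }
  // drop the final re-visit of the start pixel from the vertex list
  if (cxs.size() > 1 && cxs.back() == sx && cys.back() == sy) {
    cxs.pop_back(); cys.pop_back();
  }
  return List::create(_["perimeter"] = per,
                      _["x"] = wrap(cxs), _["y"] = wrap(cys));
}
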