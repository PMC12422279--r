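#include <Rcpp.h>
using namespace Rcpp;

// Step length: normal(mean, sd) truncated at zero (support [0, Inf)).
// sd == 0 collapses to the (non-negative) mean.
static inline double rstep(double mean, double sd) {
  if (sd <= 0.0) return mean;
  double s;
  do {
    s = R::rnorm(mean, sd);
  } while (s < 0.0);
  return s;
}

// Home-range-confined correlated random walk.
//
// The walk starts at (cx, cy), the home-range centre, with a uniform initial
// heading. Each step turns by a normal deviate (sd sd_turn, radians) and
// moves a truncated-normal step length. A proposed step landing outside the
// home-range disc of radius sqrt(r2) around the centre, or outside the
// rectangle [xmin,xmax]x[ymin,ymax], is rejected and redrawn (fresh turn and
// length) up to max_try times; after that the heading is pointed at the home
// centre and the step length capped at the distance to the centre, which by
// convexity always yields a valid position.
//
// Returns an n_steps x 2 matrix of step endpoints (the start point is not a
// row; callers hold it as the home centre).
// [[Rcpp::export]]
NumericMatrix crw_walk_cpp(int n_steps, double mean_step, double sd_step,
                           double sd_turn, double cx, double cy, double r2,
                           double xmin, double xmax, double ymin, double ymax,
                           int max_try = 100) {
  NumericMatrix out(n_steps, 2);
  double x = cx, y = cy;
  double heading = R::runif(0.0, 2.0 * M_PI);
  for (int i = 0; i < n_steps; i++) {
    bool ok = false;
    double nx = x, ny = y, nh = heading;
    for (int att = 0; att < max_try; att++) {
      double turn = (sd_turn > 0.0) ? R::rnorm(0.0, sd_turn) : 0.0;
      double len = rstep(mean_step, sd_step);
      nh = heading + turn;
      nx = x + len * cos(nh);
      ny = y + len * sin(nh);
      double dx = nx - cx, dy = ny - cy;
      if (dx * dx + dy * dy <= r2 &&
          nx >= xmin && nx <= xmax && ny >= ymin && ny <= ymax) {
        ok = true;
        break;
      }
    }
    if (!ok) {
      double dx = cx - x, dy = cy - y;
      double dist = sqrt(dx * dx + dy * dy);
      double len = rstep(mean_step, sd_step);
      if (dist > 0.0) {
        nh = atan2(dy, dx);
        if (len > dist) len = dist;
        nx = x + len * cos(nh);
        ny = y + len * sin(nh);
      } else {
        nx = x; ny = y; nh = heading;
      }
    }
    x = nx; y = ny; heading = nh;
    out(i, 0) = x;
    out(i, 1) = y;
  }
  return out;
}

// Smallest absolute difference between two angles, degrees.
// (fmod avoided deliberately: floor-based wrap keeps the symbol footprint
// to long-stable libm entry points.)
static inline double ang_diff_deg(double a, double b) {
  double d = (a - b) / 360.0;
  d = (d - std::floor(d)) * 360.0;  // in [0, 360)
  return d > 180.0 ? 360.0 - d : d;
}

// Scan trajectory step endpoints against every camera's detection zone.
// Bearing from camera to point uses the compass convention (0 = +y axis,
// clockwise positive), matching facing_deg. A point at zero distance from
// the camera is inside the zone; radius and sector boundaries are inclusive.
// t_sec are step times; a hit requires t within the camera's active window.
// Returns 1-based (step, camera) index pairs.
// [[Rcpp::export]]
List detect_scan_cpp(NumericMatrix pos, NumericVector t_sec,
                     NumericVector cam_x, NumericVector cam_y,
                     NumericVector facing_deg, NumericVector radius_m,
                     NumericVector half_deg, NumericVector act_start,
                     NumericVector act_end) {
  int n = pos.nrow(), m = cam_x.size();
  std::vector<int> step_idx, cam_idx;
  for (int i = 0; i < n; i++) {
    double x = pos(i, 0), y = pos(i, 1), t = t_sec[i];
    for (int j = 0; j < m; j++) {
      double dx = x - cam_x[j], dy = y - cam_y[j];
      double r = radius_m[j];
      if (fabs(dx) > r || fabs(dy) > r) continue;
      if (dx * dx + dy * dy > r * r) continue;
      if (t < act_start[j] || t > act_end[j]) continue;
      if (dx != 0.0 || dy != 0.0) {
        double bearing = atan2(dx, dy) * 180.0 / M_PI;  // compass
        if (ang_diff_deg(bearing, facing_deg[j]) > half_deg[j]) continue;
      }
      step_idx.push_back(i + 1);
      cam_idx.push_back(j + 1);
    }
  }
  return List::create(_["step"] = wrap(step_idx), _["camera"] = wrap(cam_idx));
}
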