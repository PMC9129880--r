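#include <Rcpp.h>
using namespace Rcpp;

// Rotate unit heading (hx,hy) towards unit target (ux,uy) by at most theta
// radians, preserving the sign of the shortest arc. A target exactly
// opposite the heading rotates counter-clockwise (atan2 convention).
static inline void rotate_towards(double &hx, double &hy,
                                  double ux, double uy, double theta) {
  double dot = hx * ux + hy * uy;
  double crs = hx * uy - hy * ux;
  double ang = std::atan2(crs, dot);
  double mag = std::fabs(ang);
  if (mag < 1e-12 || theta <= 0.0) return;
  double turn = std::min(theta, mag);
  double a = (ang >= 0.0) ? turn : -turn;
  double ct = std::cos(a), st = std::sin(a);
  double nx = ct * hx - st * hy;
  double ny = st * hx + ct * hy;
  double nrm = std::sqrt(nx * nx + ny * ny);
  hx = nx / nrm;
  hy = ny / nrm;
}

// Discrete-element update loop for one chain. Positions/headings are n x 2.
// cil_mode: 0 = off, 1 = differential (only unlike identities repolarise),
// 2 = all_pairs. identity: 0 = leader, 1 = follower. Draws all randomness
// from R's RNG stream in a fixed order (CIL/exclusion degenerate escapes,
// then n heading-noise angles per step), so results are reproducible from
// set.seed() alone and agree with the reference R step() implementation.
// [[Rcpp::export]]
List sim_core(NumericMatrix pos0, NumericMatrix head0, IntegerVector persist0,
              IntegerVector identity, NumericVector radius,
              NumericVector speed, NumericVector theta, int cil_mode,
              double eps, double coa_range, double zeta, double dt,
              NumericVector cil_push, int cil_sustained, int n_steps,
              int sample_every,
              int persist_steps, double contact_tol, int excl_passes,
              double excl_strength, double xmin, double xmax, double ymin,
              double ymax) {
  const int n = pos0.nrow();
  NumericMatrix pos(clone(pos0));
  NumericMatrix head(clone(head0));
  IntegerVector persist(clone(persist0));

  const int n_frames = n_steps / sample_every + 1;
  NumericVector out(Dimension(n_frames, n, 2));
  int frame = 0;
  for (int i = 0; i < n; ++i) {
    out[frame + n_frames * i] = pos(i, 0);
    out[frame + n_frames * (i + n)] = pos(i, 1);
  }
  ++frame;

  std::vector<double> dispx(n), dispy(n);
  // pairwise contact state: CIL fires on contact onset, not continuously
  std::vector<char> in_contact(n * n, 0);

  for (int t = 1; t <= n_steps; ++t) {
    // 1. intrinsic motility
    for (int i = 0; i < n; ++i) {
      pos(i, 0) += speed[i] * dt * head(i, 0);
      pos(i, 1) += speed[i] * dt * head(i, 1);
    }

    // 2. contact inhibition of locomotion (repolarisation at contact onset)
    if (cil_mode != 0) {
      for (int i = 0; i < n - 1; ++i) {
        for (int j = i + 1; j < n; ++j) {
          if (cil_mode == 1 && identity[i] == identity[j]) continue;
          double dx = pos(i, 0) - pos(j, 0);
          double dy = pos(i, 1) - pos(j, 1);
          double d = std::sqrt(dx * dx + dy * dy);
          bool contact = d < radius[i] + radius[j] + contact_tol;
          bool onset = contact && !in_contact[i * n + j];
          in_contact[i * n + j] = contact ? 1 : 0;
          if (!contact) continue;
          double ux, uy;
          if (d < 1e-9) {  // coincident centres: seeded random escape axis
            double a = R::runif(0.0, 2.0 * M_PI);
            ux = std::cos(a);
            uy = std::sin(a);
          } else {
            ux = dx / d;
            uy = dy / d;
          }
          // sustained repulsion: each cell recoils away from the contact
          // with a magnitude set by its own CIL intensity
          pos(i, 0) += cil_push[i] * dt * ux;
          pos(i, 1) += cil_push[i] * dt * uy;
          pos(j, 0) -= cil_push[j] * dt * ux;
          pos(j, 1) -= cil_push[j] * dt * uy;
          if (!onset && !cil_sustained) continue;
          // repolarisation away from the partner
          double hi = head(i, 0), hj = head(i, 1);
          if (theta[i] > 0.0) {
            rotate_towards(hi, hj, ux, uy, theta[i]);
            head(i, 0) = hi;
            head(i, 1) = hj;
            persist[i] = persist_steps;
          }
          double gi = head(j, 0), gj = head(j, 1);
          if (theta[j] > 0.0) {
            rotate_towards(gi, gj, -ux, -uy, theta[j]);
            head(j, 0) = gi;
            head(j, 1) = gj;
            persist[j] = persist_steps;
          }
        }
      }
    }

    // 3. co-attraction towards the centroid of the neighbourhood "at a
    // distance": the nearest non-touching cell within range on each side
    // of the focal cell along the chain (dorsoventral) axis. Touching
    // cells exert no pull, and at most one cell per side contributes, so
    // a single-file chain behaves as a train of tension links.
    if (eps > 0.0) {
      for (int i = 0; i < n; ++i) {
        int best_v = -1, best_d = -1;
        double bd_v = R_PosInf, bd_d = R_PosInf;
        for (int j = 0; j < n; ++j) {
          if (j == i) continue;
          double dx = pos(j, 0) - pos(i, 0);
          double dy = pos(j, 1) - pos(i, 1);
          double d = std::sqrt(dx * dx + dy * dy);
          if (d <= radius[i] + radius[j] || d > coa_range) continue;
          if (pos(j, 1) >= pos(i, 1)) {
            if (d < bd_v) { bd_v = d; best_v = j; }
          } else {
            if (d < bd_d) { bd_d = d; best_d = j; }
          }
        }
        int cnt = 0;
        double sx = 0.0, sy = 0.0;
        if (best_v >= 0) { sx += pos(best_v, 0); sy += pos(best_v, 1); ++cnt; }
        if (best_d >= 0) { sx += pos(best_d, 0); sy += pos(best_d, 1); ++cnt; }
        if (cnt > 0) {
          double vx = sx / cnt - pos(i, 0);
          double vy = sy / cnt - pos(i, 1);
          double d = std::sqrt(vx * vx + vy * vy);
          if (d > 1e-12) {
            dispx[i] = eps * dt * vx / d;
            dispy[i] = eps * dt * vy / d;
          } else {
            dispx[i] = dispy[i] = 0.0;
          }
        } else {
          dispx[i] = dispy[i] = 0.0;
        }
      }
      for (int i = 0; i < n; ++i) {
        pos(i, 0) += dispx[i];
        pos(i, 1) += dispy[i];
      }
    }

    // 4. volume exclusion: soft repulsive spring (cells are deformable:
    // a fraction excl_strength of the pair overlap is recovered per pass)
    for (int pass = 0; pass < excl_passes; ++pass) {
      for (int i = 0; i < n - 1; ++i) {
        for (int j = i + 1; j < n; ++j) {
          double dx = pos(i, 0) - pos(j, 0);
          double dy = pos(i, 1) - pos(j, 1);
          double d = std::sqrt(dx * dx + dy * dy);
          double target = radius[i] + radius[j];
          if (d >= target) continue;
          double ux, uy;
          if (d < 1e-9) {
            double a = R::runif(0.0, 2.0 * M_PI);
            ux = std::cos(a);
            uy = std::sin(a);
          } else {
            ux = dx / d;
            uy = dy / d;
          }
          double push = 0.5 * excl_strength * (target - d);
          pos(i, 0) += push * ux;
          pos(i, 1) += push * uy;
          pos(j, 0) -= push * ux;
          pos(j, 1) -= push * uy;
        }
      }
    }

    // 5. heading noise (suppressed while a CIL repolarisation persists);
    // one draw per agent per step in index order regardless of state
    for (int i = 0; i < n; ++i) {
      double z = R::rnorm(0.0, zeta);
      if (persist[i] > 0) {
        persist[i] -= 1;
      } else if (zeta > 0.0) {
        double ct = std::cos(z), st = std::sin(z);
        double nx = ct * head(i, 0) - st * head(i, 1);
        double ny = st * head(i, 0) + ct * head(i, 1);
        double nrm = std::sqrt(nx * nx + ny * ny);
        head(i, 0) = nx / nrm;
        head(i, 1) = ny / nrm;
      }
    }

    // 6. reflective boundaries (walls act on the cell surface)
    for (int i = 0; i < n; ++i) {
      double x0 = xmin + radius[i], x1 = xmax - radius[i];
      double y0 = ymin + radius[i], y1 = ymax - radius[i];
      for (int k = 0; k < 4; ++k) {  // at most a few reflections per step
        if (pos(i, 0) < x0) {
          pos(i, 0) = 2.0 * x0 - pos(i, 0);
          head(i, 0) = std::fabs(head(i, 0));
        } else if (pos(i, 0) > x1) {
          pos(i, 0) = 2.0 * x1 - pos(i, 0);
          head(i, 0) = -std::fabs(head(i, 0));
        } else if (pos(i, 1) < y0) {
          pos(i, 1) = 2.0 * y0 - pos(i, 1);
          head(i, 1) = std::fabs(head(i, 1));
        } else if (pos(i, 1) > y1) {
          pos(i, 1) = 2.0 * y1 - pos(i, 1);
          head(i, 1) = -std::fabs(head(i, 1));
        } else {
          break;
        }
      }
      if (!R_finite(pos(i, 0)) || !R_finite(pos(i, 1)))
        stop("non-finite position for agent %d at step %d", i + 1, t);
    }

    if (t % sample_every == 0) {
      for (int i = 0; i < n; ++i) {
        out[frame + n_frames * i] = pos(i, 0);
        out[frame + n_frames * (i + n)] = pos(i, 1);
      }
      ++frame;
    }
  }

  return List::create(_["positions"] = out, _["head"] = head,
                      _["persist"] = persist, _["pos"] = pos);
}
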