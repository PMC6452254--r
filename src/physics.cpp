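#include <Rcpp.h>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Insect robot: planar (top-down) disc body with n radially symmetric legs.
// Each leg is a rotary joint with a return spring; the foot's radial offset
// follows sin(theta).  Propulsion arises from anisotropic Coulomb-style
// friction at the feet (higher grip when the foot slides outward than
// inward), smoothed with tanh to avoid stiction chatter.
// State layout: [x, y, phi, vx, vy, omega, theta(n), thdot(n)]
// ---------------------------------------------------------------------------

// [[Rcpp::export]]
List insect_substeps(NumericVector state, NumericVector torque, List params,
                     int n_sub, double dt) {
  const int n = as<int>(params["n_legs"]);
  const double M = as<double>(params["mass"]);
  const double Iz = as<double>(params["I_body"]);
  const double R0 = as<double>(params["body_radius"]);
  const double L0 = as<double>(params["leg_offset"]);
  const double L1 = as<double>(params["leg_stroke"]);
  const double Il = as<double>(params["leg_inertia"]);
  const double K = as<double>(params["K"]);
  const double b = as<double>(params["leg_damping"]);
  const double mu_grip = as<double>(params["mu_grip"]);
  const double load_gain = as<double>(params["load_gain"]);
  const double v0 = as<double>(params["v_smooth"]);
  const double th_max = as<double>(params["theta_max"]);
  const double k_lim = as<double>(params["limit_stiffness"]);
  const double c_lin = as<double>(params["body_lin_damp"]);
  const double c_rot = as<double>(params["body_rot_damp"]);
  const double g = as<double>(params["gravity"]);
  const double arena = as<double>(params["arena_half"]); // Inf => no walls
  const double wall_k = as<double>(params["wall_stiffness"]);
  const double wall_d = as<double>(params["wall_damping"]);
  const double mu_wall = as<double>(params["mu_wall"]);
  const double N_foot = M * g / n;

  NumericVector st = clone(state);
  double x = st[0], y = st[1], phi = st[2];
  double vx = st[3], vy = st[4], om = st[5];
  std::vector<double> th(n), thd(n);
  for (int i = 0; i < n; ++i) { th[i] = st[6 + i]; thd[i] = st[6 + n + i]; }

  bool wall_contact = false;
  double wall_fx = 0.0, wall_fy = 0.0; // last-substep wall force
  double wall_px = 0.0, wall_py = 0.0; // contact point (disc rim)

  for (int s = 0; s < n_sub; ++s) {
    double Fx = 0.0, Fy = 0.0, T = 0.0;
    // legs
    for (int i = 0; i < n; ++i) {
      double psi = phi + 2.0 * M_PI * i / n;
      double ex = std::cos(psi), ey = std::sin(psi);
      double r = R0 + L0 + L1 * std::sin(th[i]);
      double px = x + r * ex, py = y + r * ey;
      // foot velocity: base + rotation + radial extension
      double rx = px - x, ry = py - y;
      double dr = L1 * std::cos(th[i]) * thd[i];
      double vfx = vx - om * ry + dr * ex;
      double vfy = vy + om * rx + dr * ey;
      // the foot presses the ground in proportion to its outward stroke
      // (press-and-push; the retracting foot is unloaded and slides free)
      double load = load_gain * std::max(0.0, std::sin(th[i]));
      double Ni = N_foot * load;
      double vr = vfx * ex + vfy * ey;      // radial slip component
      double vt = -vfx * ey + vfy * ex;     // tangential slip component
      double Fr = -mu_grip * Ni * std::tanh(vr / v0);
      double Ft = -mu_grip * Ni * std::tanh(vt / v0);
      double ffx = Fr * ex - Ft * ey;
      double ffy = Fr * ey + Ft * ex;
      Fx += ffx; Fy += ffy;
      T += rx * ffy - ry * ffx;
      // leg joint dynamics
      double tau = torque[i] - K * th[i] - b * thd[i]
                 + L1 * std::cos(th[i]) * Fr;
      if (th[i] > th_max) tau -= k_lim * (th[i] - th_max) + 0.01 * thd[i];
      if (th[i] < -th_max) tau -= k_lim * (th[i] + th_max) + 0.01 * thd[i];
      thd[i] += dt * tau / Il;
      th[i] += dt * thd[i];
    }
    // arena walls (square, half-width `arena`)
    if (R_finite(arena)) {
      double lim = arena - R0;
      double pen, Nf;
      if (x > lim) {
        pen = x - lim; Nf = wall_k * pen + wall_d * std::max(vx, 0.0);
        if (Nf > 0) { Fx -= Nf; Fy += -mu_wall * Nf * std::tanh(vy / v0);
          wall_contact = true; wall_fx = -Nf; wall_fy = 0;
          wall_px = x + R0; wall_py = y; }
      }
      if (x < -lim) {
        pen = -lim - x; Nf = wall_k * pen + wall_d * std::max(-vx, 0.0);
        if (Nf > 0) { Fx += Nf; Fy += -mu_wall * Nf * std::tanh(vy / v0);
          wall_contact = true; wall_fx = Nf; wall_fy = 0;
          wall_px = x - R0; wall_py = y; }
      }
      if (y > lim) {
        pen = y - lim; Nf = wall_k * pen + wall_d * std::max(vy, 0.0);
        if (Nf > 0) { Fy -= Nf; Fx += -mu_wall * Nf * std::tanh(vx / v0);
          wall_contact = true; wall_fx = 0; wall_fy = -Nf;
          wall_px = x; wall_py = y + R0; }
      }
      if (y < -lim) {
        pen = -lim - y; Nf = wall_k * pen + wall_d * std::max(-vy, 0.0);
        if (Nf > 0) { Fy += Nf; Fx += -mu_wall * Nf * std::tanh(vx / v0);
          wall_contact = true; wall_fx = 0; wall_fy = Nf;
          wall_px = x; wall_py = y - R0; }
      }
    }
    // base integration (semi-implicit Euler)
    vx += dt * (Fx - c_lin * vx) / M;
    vy += dt * (Fy - c_lin * vy) / M;
    x += dt * vx; y += dt * vy;
    om += dt * (T - c_rot * om) / Iz;
    phi += dt * om;
    if (!R_finite(x) || !R_finite(vx) || !R_finite(th[0]))
      stop("insect dynamics diverged at substep %d", s + 1);
  }

  st[0] = x; st[1] = y; st[2] = phi; st[3] = vx; st[4] = vy; st[5] = om;
  for (int i = 0; i < n; ++i) { st[6 + i] = th[i]; st[6 + n + i] = thd[i]; }

  double ke = 0.5 * M * (vx * vx + vy * vy) + 0.5 * Iz * om * om;
  double pe = 0.0;
  for (int i = 0; i < n; ++i) {
    ke += 0.5 * Il * thd[i] * thd[i];
    pe += 0.5 * K * th[i] * th[i];
  }
  return List::create(_["state"] = st, _["energy"] = ke + pe,
                      _["wall_contact"] = wall_contact,
                      _["wall_force"] = NumericVector::create(wall_fx, wall_fy),
                      _["wall_point"] = NumericVector::create(wall_px, wall_py));
}

// ---------------------------------------------------------------------------
// Fetus: sagittal 2D articulated chain.  Joints are rotational with return
// springs toward a rest (flexed) posture; the base (lower trunk proximal
// end) translates and rotates under gravity/buoyancy, fluid drag and
// contact forces.  Contact forces on a taxel are propagated as torques to
// every joint between that taxel's segment and the root.
// State layout: [x, y, phi, vx, vy, omega, theta(nj), thdot(nj)]
// ---------------------------------------------------------------------------

struct FetusBody {
  int nseg, njoint, ntax;
  std::vector<double> seg_len, seg_mass;
  std::vector<int> seg_parent_joint;           // -1 for root
  std::vector<int> joint_parent_seg, joint_child_seg;
  std::vector<double> joint_anchor, joint_rest, joint_K, joint_damp,
      joint_fluid, joint_min, joint_max, joint_I;
  std::vector<int> anc;                        // njoint x nseg, col-major
  std::vector<int> tax_seg;
  std::vector<double> tax_frac, tax_side;
  double M, I_base;
};

static FetusBody unpack_body(const List &cb) {
  FetusBody B;
  B.nseg = as<int>(cb["n_seg"]); B.njoint = as<int>(cb["n_joint"]);
  B.ntax = as<int>(cb["n_tax"]);
  B.seg_len = as<std::vector<double> >(cb["seg_len"]);
  B.seg_mass = as<std::vector<double> >(cb["seg_mass"]);
  B.seg_parent_joint = as<std::vector<int> >(cb["seg_parent_joint"]);
  B.joint_parent_seg = as<std::vector<int> >(cb["joint_parent_seg"]);
  B.joint_child_seg = as<std::vector<int> >(cb["joint_child_seg"]);
  B.joint_anchor = as<std::vector<double> >(cb["joint_anchor"]);
  B.joint_rest = as<std::vector<double> >(cb["joint_rest"]);
  B.joint_K = as<std::vector<double> >(cb["joint_K"]);
  B.joint_damp = as<std::vector<double> >(cb["joint_damp"]);
  B.joint_fluid = as<std::vector<double> >(cb["joint_fluid"]);
  B.joint_min = as<std::vector<double> >(cb["joint_min"]);
  B.joint_max = as<std::vector<double> >(cb["joint_max"]);
  B.joint_I = as<std::vector<double> >(cb["joint_I"]);
  B.anc = as<std::vector<int> >(cb["ancestor"]);
  B.tax_seg = as<std::vector<int> >(cb["tax_seg"]);
  B.tax_frac = as<std::vector<double> >(cb["tax_frac"]);
  B.tax_side = as<std::vector<double> >(cb["tax_side"]);
  B.M = as<double>(cb["mass_total"]);
  B.I_base = as<double>(cb["I_base"]);
  return B;
}

// forward kinematics: segment start points & angles, joint anchors,
// taxel positions & velocities, segment centres of mass.
static void fetus_fk(const FetusBody &B, const double *st,
                     std::vector<double> &segx, std::vector<double> &segy,
                     std::vector<double> &sega,
                     std::vector<double> &jx, std::vector<double> &jy,
                     std::vector<double> &taxx, std::vector<double> &taxy,
                     std::vector<double> &taxvx, std::vector<double> &taxvy,
                     std::vector<double> &comx, std::vector<double> &comy) {
  const double x = st[0], y = st[1], phi = st[2];
  const double vx = st[3], vy = st[4], om = st[5];
  const double *th = st + 6;
  const double *thd = st + 6 + B.njoint;
  segx[0] = x; segy[0] = y; sega[0] = phi;
  for (int s = 1; s < B.nseg; ++s) {
    int j = B.seg_parent_joint[s];
    int p = B.joint_parent_seg[j];
    double ax = segx[p] + B.joint_anchor[j] * B.seg_len[p] * std::cos(sega[p]);
    double ay = segy[p] + B.joint_anchor[j] * B.seg_len[p] * std::sin(sega[p]);
    jx[j] = ax; jy[j] = ay;
    sega[s] = sega[p] + B.joint_rest[j] + th[j];
    segx[s] = ax; segy[s] = ay;
  }
  for (int s = 0; s < B.nseg; ++s) {
    comx[s] = segx[s] + 0.5 * B.seg_len[s] * std::cos(sega[s]);
    comy[s] = segy[s] + 0.5 * B.seg_len[s] * std::sin(sega[s]);
  }
  for (int t = 0; t < B.ntax; ++t) {
    int s = B.tax_seg[t];
    double px = segx[s] + B.tax_frac[t] * B.seg_len[s] * std::cos(sega[s]);
    double py = segy[s] + B.tax_frac[t] * B.seg_len[s] * std::sin(sega[s]);
    taxx[t] = px; taxy[t] = py;
    // velocity: base + base rotation + ancestor joint rotations
    double tvx = vx - om * (py - y);
    double tvy = vy + om * (px - x);
    for (int j = 0; j < B.njoint; ++j) {
      if (B.anc[j + B.njoint * s]) {
        tvx += -thd[j] * (py - jy[j]);
        tvy += thd[j] * (px - jx[j]);
      }
    }
    taxvx[t] = tvx; taxvy[t] = tvy;
  }
}

// [[Rcpp::export]]
List fetus_substeps(NumericVector state, NumericVector joint_torque,
                    List cbody, List env, int n_sub, double dt) {
  FetusBody B = unpack_body(cbody);
  const int nj = B.njoint;
  const std::string kind = as<std::string>(env["kind"]);
  const bool fluid = (kind == "uterus_fluid");
  const bool ground = (kind == "flat_plane" || kind == "walled_arena");
  const double g = as<double>(env["gravity_g"]);
  const double buoy = as<double>(env["buoyancy"]);
  const double g_eff = g * (1.0 - (fluid ? buoy : 0.0));
  const double drag_lin = fluid ? as<double>(env["drag_linear"]) : 0.0;
  const double R_u = fluid ? as<double>(env["radius"]) : 0.0;
  const double wall_k = as<double>(env["wall_stiffness"]);
  const double wall_d = as<double>(env["wall_damping"]);
  const double gnd_k = as<double>(env["ground_stiffness"]);
  const double gnd_d = as<double>(env["ground_damping"]);
  const double mu = as<double>(env["friction_mu"]);
  const double v0 = as<double>(env["v_smooth"]);
  const double k_lim = as<double>(cbody["limit_stiffness"]);

  NumericVector st = clone(state);
  double *p = REAL(st);

  std::vector<double> segx(B.nseg), segy(B.nseg), sega(B.nseg),
      jx(nj), jy(nj), taxx(B.ntax), taxy(B.ntax), taxvx(B.ntax),
      taxvy(B.ntax), comx(B.nseg), comy(B.nseg);
  NumericVector tax_contact(B.ntax);
  double imp_x = 0.0, imp_y = 0.0;  // accumulated contact impulse

  for (int s = 0; s < n_sub; ++s) {
    fetus_fk(B, p, segx, segy, sega, jx, jy, taxx, taxy, taxvx, taxvy,
             comx, comy);
    double x = p[0], y = p[1];
    double vx = p[3], vy = p[4], om = p[5];
    double *th = p + 6, *thd = p + 6 + nj;

    double Fx = 0.0, Fy = -B.M * g_eff, T = 0.0;
    std::vector<double> jtau(nj, 0.0);
    // gravity torques on joints from segment masses
    if (g_eff != 0.0) {
      for (int sg = 1; sg < B.nseg; ++sg) {
        double fgy = -B.seg_mass[sg] * g_eff;
        for (int j = 0; j < nj; ++j)
          if (B.anc[j + nj * sg]) jtau[j] += (comx[sg] - jx[j]) * fgy;
      }
    }
    std::fill(tax_contact.begin(), tax_contact.end(), 0.0);
    // taxel contacts
    for (int t = 0; t < B.ntax; ++t) {
      double fx = 0.0, fy = 0.0;
      if (ground && taxy[t] < 0.0) {
        double N = gnd_k * (-taxy[t]) - gnd_d * taxvy[t];
        if (N > 0.0) {
          fy += N;
          fx += -mu * N * std::tanh(taxvx[t] / v0);
        }
      }
      if (fluid) {
        double r = std::sqrt(taxx[t] * taxx[t] + taxy[t] * taxy[t]);
        if (r > R_u && r > 1e-12) {
          double nx = -taxx[t] / r, ny = -taxy[t] / r; // inward normal
          double vn = taxvx[t] * (-nx) + taxvy[t] * (-ny); // outward speed
          double N = wall_k * (r - R_u) + wall_d * std::max(vn, 0.0);
          fx += N * nx; fy += N * ny;
        }
      }
      if (fx != 0.0 || fy != 0.0) {
        double fmag = std::sqrt(fx * fx + fy * fy);
        tax_contact[t] = fmag;
        imp_x += fx * dt; imp_y += fy * dt;
        Fx += fx; Fy += fy;
        T += (taxx[t] - x) * fy - (taxy[t] - y) * fx;
        int sg = B.tax_seg[t];
        for (int j = 0; j < nj; ++j)
          if (B.anc[j + nj * sg])
            jtau[j] += (taxx[t] - jx[j]) * fy - (taxy[t] - jy[j]) * fx;
      }
    }
    // joint integration
    for (int j = 0; j < nj; ++j) {
      double tau = joint_torque[j] + jtau[j]
                 - B.joint_K[j] * th[j]
                 - (B.joint_damp[j] + (fluid ? B.joint_fluid[j] : 0.0)) * thd[j];
      if (th[j] > B.joint_max[j]) {
        tau -= k_lim * (th[j] - B.joint_max[j]);
        if (thd[j] > 0.0) tau -= 0.05 * k_lim * thd[j];
      }
      if (th[j] < B.joint_min[j]) {
        tau -= k_lim * (th[j] - B.joint_min[j]);
        if (thd[j] < 0.0) tau -= 0.05 * k_lim * thd[j];
      }
      thd[j] += dt * tau / B.joint_I[j];
      th[j] += dt * thd[j];
    }
    // base integration
    double c_lin = drag_lin * B.M;
    vx += dt * (Fx - c_lin * vx) / B.M;
    vy += dt * (Fy - c_lin * vy) / B.M;
    p[0] = x + dt * vx; p[1] = y + dt * vy;
    p[3] = vx; p[4] = vy;
    double c_rot = as<double>(env["rot_damping"]) * B.I_base;
    om += dt * (T - c_rot * om) / B.I_base;
    p[5] = om; p[2] += dt * om;
    if (!R_finite(p[0]) || !R_finite(th[0]))
      stop("fetus dynamics diverged at substep %d", s + 1);
  }

  // final kinematics for sensing
  fetus_fk(B, p, segx, segy, sega, jx, jy, taxx, taxy, taxvx, taxvy,
           comx, comy);
  NumericVector tax_speed(B.ntax), tax_dynp(B.ntax);
  for (int t = 0; t < B.ntax; ++t) {
    tax_speed[t] = std::sqrt(taxvx[t] * taxvx[t] + taxvy[t] * taxvy[t]);
    // dynamic fluid pressure on the leading surface: the outward normal
    // of this taxel's skin side is the segment direction rotated +-90 deg
    int sg = B.tax_seg[t];
    double nx = -std::sin(sega[sg]) * B.tax_side[t];
    double ny = std::cos(sega[sg]) * B.tax_side[t];
    tax_dynp[t] = std::max(0.0, taxvx[t] * nx + taxvy[t] * ny);
  }

  // mechanical energy (kinetic + springs + gravity + contact springs)
  double ke = 0.5 * B.M * (p[3] * p[3] + p[4] * p[4])
            + 0.5 * B.I_base * p[5] * p[5];
  double pe = B.M * g_eff * p[1];
  // use center-of-mass gravity instead: sum over segments
  pe = 0.0;
  for (int sg = 0; sg < B.nseg; ++sg) pe += B.seg_mass[sg] * g_eff * comy[sg];
  for (int j = 0; j < nj; ++j) {
    ke += 0.5 * B.joint_I[j] * p[6 + nj + j] * p[6 + nj + j];
    pe += 0.5 * B.joint_K[j] * p[6 + j] * p[6 + j];
  }
  for (int t = 0; t < B.ntax; ++t) {
    if (ground && taxy[t] < 0.0) pe += 0.5 * gnd_k * taxy[t] * taxy[t];
    if (fluid) {
      double r = std::sqrt(taxx[t] * taxx[t] + taxy[t] * taxy[t]);
      if (r > R_u) pe += 0.5 * wall_k * (r - R_u) * (r - R_u);
    }
  }

  return List::create(_["state"] = st,
                      _["tax_x"] = NumericVector(taxx.begin(), taxx.end()),
                      _["tax_y"] = NumericVector(taxy.begin(), taxy.end()),
                      _["tax_speed"] = tax_speed,
                      _["tax_dynp"] = tax_dynp,
                      _["tax_contact"] = tax_contact,
                      _["contact_impulse"] =
                          NumericVector::create(imp_x, imp_y),
                      _["energy"] = ke + pe,
                      _["head_x"] = segx, _["head_y"] = segy,
                      _["seg_angle"] = sega);
}

// Kinematic helper: positions/velocities/contact penalties for a single
// state, used by sense() and scripted (non-dynamic) trajectories.
// [[Rcpp::export]]
List fetus_kinematics(NumericVector state, List cbody) {
  FetusBody B = unpack_body(cbody);
  std::vector<double> segx(B.nseg), segy(B.nseg), sega(B.nseg),
      jx(B.njoint), jy(B.njoint), taxx(B.ntax), taxy(B.ntax),
      taxvx(B.ntax), taxvy(B.ntax), comx(B.nseg), comy(B.nseg);
  fetus_fk(B, REAL(state), segx, segy, sega, jx, jy, taxx, taxy,
           taxvx, taxvy, comx, comy);
  return List::create(
      _["seg_x"] = NumericVector(segx.begin(), segx.end()),
      _["seg_y"] = NumericVector(segy.begin(), segy.end()),
      _["seg_angle"] = NumericVector(sega.begin(), sega.end()),
      _["joint_x"] = NumericVector(jx.begin(), jx.end()),
      _["joint_y"] = NumericVector(jy.begin(), jy.end()),
      _["tax_x"] = NumericVector(taxx.begin(), taxx.end()),
      _["tax_y"] = NumericVector(taxy.begin(), taxy.end()),
      _["tax_vx"] = NumericVector(taxvx.begin(), taxvx.end()),
      _["tax_vy"] = NumericVector(taxvy.begin(), taxvy.end()));
}

// Pseudo-contact forces for self-touch between two taxel groups
// (hand/face): spring force below the touch distance, accumulated on
// both taxels. ia/ib are 0-based indices.
// [[Rcpp::export]]
NumericVector self_touch_cpp(NumericVector tax_x, NumericVector tax_y,
                             IntegerVector ia, IntegerVector ib,
                             double d_touch, double k_touch) {
  NumericVector f(tax_x.size());
  const double d2max = d_touch * d_touch;
  for (int i = 0; i < ia.size(); ++i) {
    double xi = tax_x[ia[i]], yi = tax_y[ia[i]];
    for (int j = 0; j < ib.size(); ++j) {
      double dx = xi - tax_x[ib[j]], dy = yi - tax_y[ib[j]];
      double d2 = dx * dx + dy * dy;
      if (d2 < d2max) {
        double press = k_touch * (d_touch - std::sqrt(d2));
        f[ia[i]] += press;
        f[ib[j]] += press;
      }
    }
  }
  return f;
}
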