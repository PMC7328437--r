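#include <Rcpp.h>
#include <vector>
#include <queue>
#include <unordered_map>
#include <cmath>
using namespace Rcpp;

// ---------------------------------------------------------------------------
// Street network with CSR adjacency and A* shortest paths.
// Edge lengths are metres and must be >= Euclidean distance between the
// endpoints, which makes the straight-line heuristic admissible.
// ---------------------------------------------------------------------------

struct Graph {
  int n;
  std::vector<double> x, y;
  std::vector<int> head;            // CSR offsets, size n+1
  std::vector<int> adj;             // neighbour node ids
  std::vector<double> w;            // edge lengths
};

static Graph build_graph(const NumericVector& nx, const NumericVector& ny,
                         const IntegerVector& eu, const IntegerVector& ev,
                         const NumericVector& el) {
  Graph g;
  g.n = nx.size();
  g.x.assign(nx.begin(), nx.end());
  g.y.assign(ny.begin(), ny.end());
  int m = eu.size();
  std::vector<int> deg(g.n, 0);
  for (int e = 0; e < m; ++e) { deg[eu[e] - 1]++; deg[ev[e] - 1]++; }
  g.head.assign(g.n + 1, 0);
  for (int i = 0; i < g.n; ++i) g.head[i + 1] = g.head[i] + deg[i];
  g.adj.assign(2 * m, 0);
  g.w.assign(2 * m, 0.0);
  std::vector<int> pos(g.head.begin(), g.head.end() - 1);
  for (int e = 0; e < m; ++e) {
    int u = eu[e] - 1, v = ev[e] - 1;
    g.adj[pos[u]] = v; g.w[pos[u]++] = el[e];
    g.adj[pos[v]] = u; g.w[pos[v]++] = el[e];
  }
  return g;
}

static double euclid(double ax, double ay, double bx, double by) {
  double dx = ax - bx, dy = ay - by;
  return std::sqrt(dx * dx + dy * dy);
}

// A* search; returns node path (0-based) origin..dest, cost, and the number
// of nodes expanded (popped with finalised distance).
static bool astar(const Graph& g, int from, int to,
                  std::vector<int>& path, double& cost, int& expanded) {
  const double INF = std::numeric_limits<double>::infinity();
  std::vector<double> dist(g.n, INF);
  std::vector<int> parent(g.n, -1);
  std::vector<char> closed(g.n, 0);
  typedef std::pair<double, int> QE;    // (f = dist + heuristic, node)
  std::priority_queue<QE, std::vector<QE>, std::greater<QE> > pq;
  dist[from] = 0.0;
  pq.push(QE(euclid(g.x[from], g.y[from], g.x[to], g.y[to]), from));
  expanded = 0;
  while (!pq.empty()) {
    int u = pq.top().second; pq.pop();
    if (closed[u]) continue;
    closed[u] = 1;
    ++expanded;
    if (u == to) break;
    for (int k = g.head[u]; k < g.head[u + 1]; ++k) {
      int v = g.adj[k];
      if (closed[v]) continue;
      double nd = dist[u] + g.w[k];
      if (nd < dist[v]) {
        dist[v] = nd;
        parent[v] = u;
        pq.push(QE(nd + euclid(g.x[v], g.y[v], g.x[to], g.y[to]), v));
      }
    }
  }
  if (dist[to] == INF) return false;
  cost = dist[to];
  path.clear();
  for (int v = to; v != -1; v = parent[v]) path.push_back(v);
  std::reverse(path.begin(), path.end());
  return true;
}

// [[Rcpp::export]]
List astar_cpp(NumericVector node_x, NumericVector node_y,
               IntegerVector edge_u, IntegerVector edge_v,
               NumericVector edge_len, int from, int to) {
  Graph g = build_graph(node_x, node_y, edge_u, edge_v, edge_len);
  std::vector<int> path;
  double cost = 0.0;
  int expanded = 0;
  if (from < 1 || from > g.n || to < 1 || to > g.n)
    stop("node id out of range");
  if (!astar(g, from - 1, to - 1, path, cost, expanded))
    stop("no path between nodes %d and %d", from, to);
  IntegerVector p(path.size());
  for (size_t i = 0; i < path.size(); ++i) p[i] = path[i] + 1;
  return List::create(_["path"] = p, _["cost"] = cost,
                      _["expanded"] = expanded);
}

// ---------------------------------------------------------------------------
// Geometry: minimum distance from segment (a,b) to point c.
// ---------------------------------------------------------------------------
static double seg_point_dist(double ax, double ay, double bx, double by,
                             double cx, double cy) {
  double vx = bx - ax, vy = by - ay;
  double L2 = vx * vx + vy * vy;
  if (L2 <= 0.0) return euclid(ax, ay, cx, cy);
  double t = ((cx - ax) * vx + (cy - ay) * vy) / L2;
  if (t < 0.0) t = 0.0; else if (t > 1.0) t = 1.0;
  return euclid(ax + t * vx, ay + t * vy, cx, cy);
}

// [[Rcpp::export]]
double seg_point_dist_cpp(double ax, double ay, double bx, double by,
                          double cx, double cy) {
  return seg_point_dist(ax, ay, bx, by, cx, cy);
}

// ---------------------------------------------------------------------------
// Time windows.  Membership of minute-of-day t in [ws, we) shifted by
// `off` minutes, wrapping at midnight.  ws == we denotes an empty window;
// we may be 1440 so [0, 1440) covers the whole day.
// ---------------------------------------------------------------------------
static bool in_window(double t, double ws, double we, double off) {
  if (ws == we) return false;
  double tt = t - off;
  tt -= 1440.0 * std::floor(tt / 1440.0);   // wrap into [0, 1440)
  if (tt >= 1440.0) tt = 0.0;
  if (ws < we) return tt >= ws && tt < we;
  return tt >= ws || tt < we;       // wraps midnight
}

// [[Rcpp::export]]
bool in_window_cpp(double t, double ws, double we, double off) {
  return in_window(t, ws, we, off);
}

// ---------------------------------------------------------------------------
// Full simulation of one replicate.
//
// Activities are coded 1..7 in canonical order:
//   1 at_home, 2 work, 3 shop_food, 4 shop_leisure, 5 lunch_out,
//   6 evening_social, 7 sports
// Building functions 1..7:
//   1 residential, 2 office, 3 supermarket, 4 leisure_shop, 5 restaurant,
//   6 pub, 7 sports_facility
// Groups: 1 commuter, 2 retired.
//
// Per 5-minute step and agent (agents visited in an order reshuffled each
// step from the replicate RNG), decide first, then perform:
//   1. a free agent whose elapsed time has reached its minimal duration
//      re-evaluates: argmax of background + time intensity, ties keep the
//      current activity, otherwise first in canonical order; a new
//      flexible activity is allocated to a uniform random building of the
//      required function within an iteratively doubled radius, and travel
//      towards it starts immediately;
//   2. background update: the activity performed this step decays by
//      decay_rate (clipped at 0); every other applicable activity grows
//      by grow_rate * rate_mult (travelling performs nothing: all grow);
//   3. travelling agents advance speed*dt metres along their A* route,
//      crossing events are recorded when a step sub-segment enters a
//      sensor disc from outside; on arrival the destination activity
//      starts with its elapsed clock at 0 (it is performed, logged and
//      begins decaying from the next step).
// A logged episode of an activity therefore spans exactly its performed
// steps, never fewer than the agent's minimal duration.
// ---------------------------------------------------------------------------

struct AgentRt {
  int group;            // 0 commuter, 1 retired
  int cur;              // current activity 0..6 (when not travelling)
  int elapsed;          // steps performed in current activity
  bool travelling;
  int node;             // current node when not travelling
  // travel state
  std::vector<int> path;
  int seg;              // index of segment being traversed
  double seg_pos;       // metres advanced along current segment
  int dest_act;
  int dest_node;
  double px, py;        // current coordinates
  double B[7];
  int min_dur[7];       // agent-specific minimal durations (steps)
};

// [[Rcpp::export]]
List run_engine_cpp(List town, List agents, List params, List config) {
  // --- town ---
  NumericVector node_x = town["node_x"], node_y = town["node_y"];
  IntegerVector edge_u = town["edge_u"], edge_v = town["edge_v"];
  NumericVector edge_len = town["edge_len"];
  IntegerVector b_node = town["building_node"];
  NumericVector b_x = town["building_x"], b_y = town["building_y"];
  IntegerVector b_fun = town["building_fun"];
  NumericVector s_x = town["sensor_x"], s_y = town["sensor_y"];
  NumericVector s_r = town["sensor_r"];
  Graph g = build_graph(node_x, node_y, edge_u, edge_v, edge_len);
  int n_b = b_node.size(), n_s = s_x.size();

  std::vector< std::vector<int> > by_fun(8);
  for (int b = 0; b < n_b; ++b) by_fun[b_fun[b]].push_back(b);

  // --- agents ---
  IntegerVector group = agents["group"];
  IntegerVector home_b = agents["home_building"];
  IntegerVector work_b = agents["work_building"];
  NumericVector offset = agents["offset_min"];
  NumericMatrix rate_mult = agents["rate_mult"];   // n x 7
  NumericMatrix dur_mult = agents["dur_mult"];     // n x 7
  int n = group.size();

  // --- params: 2 x 7 matrices (group x activity) ---
  NumericMatrix grow = params["grow"], decay = params["decay"],
    amp = params["amplitude"], ws = params["window_start"],
    we = params["window_end"], init_max = params["init_max"];
  NumericMatrix min_dur = params["min_dur_steps"];
  IntegerMatrix active = params["active"];
  // required building function per activity (0 = anchored / none)
  int req_fun[7] = {0, 0, 3, 4, 5, 6, 7};

  // --- config ---
  int step_min = as<int>(config["step_minutes"]);
  int n_days = as<int>(config["n_days"]);
  double speed = as<double>(config["walking_speed_mps"]);
  double r0 = as<double>(config["initial_radius_m"]);
  int max_doubl = as<int>(config["max_doublings"]);
  double jitter_min = as<double>(config["daily_jitter_min"]);
  int steps_per_day = 1440 / step_min;
  double step_dist = speed * step_min * 60.0;
  int report_day = n_days - 1;

  // --- state ---
  std::vector<AgentRt> st(n);
  std::vector<char> inside(static_cast<size_t>(n) * n_s, 0);
  NumericMatrix jitter(n, 7);
  IntegerMatrix footfall(n_s, 24);
  IntegerMatrix log_mat(n, steps_per_day);
  std::vector<int> ev_agent, ev_sensor, ev_step;

  for (int i = 0; i < n; ++i) {
    AgentRt& a = st[i];
    a.group = group[i] - 1;
    a.cur = 0;                       // at_home
    a.travelling = false;
    int hb = home_b[i] - 1;
    a.node = b_node[hb] - 1;
    a.px = g.x[a.node]; a.py = g.y[a.node];
    for (int k = 0; k < 7; ++k) {
      a.B[k] = 0.0;
      a.min_dur[k] = 1;
      if (active(a.group, k)) {
        if (init_max(a.group, k) > 0)
          a.B[k] = unif_rand() * init_max(a.group, k);
        int md = (int)std::ceil(min_dur(a.group, k) * dur_mult(i, k) - 1e-9);
        a.min_dur[k] = md < 1 ? 1 : md;
      }
    }
    a.elapsed = a.min_dur[0];        // free to choose immediately
    for (int sN = 0; sN < n_s; ++sN)
      inside[(size_t)i * n_s + sN] =
        euclid(a.px, a.py, s_x[sN], s_y[sN]) <= s_r[sN] ? 1 : 0;
  }

  std::vector<int> order(n);
  for (int i = 0; i < n; ++i) order[i] = i;

  // path cache keyed by origin*n_nodes + dest
  std::unordered_map<long long, std::vector<int> > path_cache;

  int total_steps = n_days * steps_per_day;
  for (int s = 0; s < total_steps; ++s) {
    int day = s / steps_per_day;
    int sod = s % steps_per_day;               // step of day
    double tod = sod * (double)step_min;       // minute of day
    bool record = (day == report_day);

    if (sod == 0) {                            // redraw daily window jitter
      for (int i = 0; i < n; ++i)
        for (int k = 0; k < 7; ++k)
          jitter(i, k) = jitter_min > 0 ? (unif_rand() * 2.0 - 1.0) * jitter_min : 0.0;
    }

    // Fisher-Yates reshuffle of the update order
    for (int i = n - 1; i > 0; --i) {
      int j = (int)(unif_rand() * (i + 1));
      if (j > i) j = i;
      std::swap(order[i], order[j]);
    }

    for (int oi = 0; oi < n; ++oi) {
      int i = order[oi];
      AgentRt& a = st[i];
      int grp = a.group;

      // 1. decide first, then perform: a free agent whose minimal
      // duration has elapsed re-evaluates before this step is spent
      if (!a.travelling && a.elapsed >= a.min_dur[a.cur]) {
        double best = -1.0;
        int best_k = -1;
        double tot_cur = -1.0;
        for (int k = 0; k < 7; ++k) {
          if (!active(grp, k)) continue;
          double A = in_window(tod, ws(grp, k), we(grp, k),
                               offset[i] + jitter(i, k)) ? amp(grp, k) : 0.0;
          double tot = a.B[k] + A;
          if (k == a.cur) tot_cur = tot;
          if (tot > best) { best = tot; best_k = k; }
        }
        if (best_k < 0) stop("agent %d has no applicable activities", i + 1);
        int chosen = (tot_cur >= best) ? a.cur : best_k;
        if (chosen != a.cur) {
          int db = -1;
          if (chosen == 0) db = home_b[i] - 1;
          else if (chosen == 1) db = work_b[i] - 1;
          else {
            int fun = req_fun[chosen];
            const std::vector<int>& cand = by_fun[fun];
            double r = r0;
            std::vector<int> hits;
            for (int dbl = 0; dbl <= max_doubl; ++dbl, r *= 2.0) {
              hits.clear();
              for (size_t c = 0; c < cand.size(); ++c)
                if (euclid(a.px, a.py, b_x[cand[c]], b_y[cand[c]]) <= r)
                  hits.push_back(cand[c]);
              if (!hits.empty()) break;
            }
            if (hits.empty())
              stop("no building with function %d within search radius at step %d",
                   fun, s);
            int pick = (int)(unif_rand() * hits.size());
            if (pick >= (int)hits.size()) pick = hits.size() - 1;
            db = hits[pick];
          }
          int dn = b_node[db] - 1;
          if (dn == a.node) {
            a.cur = chosen;
            a.elapsed = 0;
          } else {
            long long key = (long long)a.node * g.n + dn;
            std::unordered_map<long long, std::vector<int> >::iterator it =
              path_cache.find(key);
            if (it == path_cache.end()) {
              std::vector<int> path;
              double cost; int exp_;
              if (!astar(g, a.node, dn, path, cost, exp_))
                stop("agent %d: no route from node %d to node %d",
                     i + 1, a.node + 1, dn + 1);
              it = path_cache.insert(std::make_pair(key, path)).first;
            }
            a.travelling = true;
            a.path = it->second;
            a.seg = 0;
            a.seg_pos = 0.0;
            a.dest_act = chosen;
            a.dest_node = dn;
          }
        }
      }

      // 2. perform this step: background dynamics (travel performs
      // nothing, so every applicable activity grows)
      for (int k = 0; k < 7; ++k) {
        if (!active(grp, k)) continue;
        if (!a.travelling && k == a.cur) {
          a.B[k] -= decay(grp, k);
          if (a.B[k] < 0) a.B[k] = 0;
        } else {
          a.B[k] += grow(grp, k) * rate_mult(i, k);
        }
      }

      if (a.travelling) {
        // 2. advance along route, sub-segment by sub-segment
        double remaining = step_dist;
        while (remaining > 0.0) {
          int u = a.path[a.seg], v = a.path[a.seg + 1];
          double seg_len = 0.0;
          // edge length between u and v
          for (int k = g.head[u]; k < g.head[u + 1]; ++k)
            if (g.adj[k] == v) { seg_len = g.w[k]; break; }
          double left = seg_len - a.seg_pos;
          double adv = remaining < left ? remaining : left;
          double f0 = seg_len > 0 ? a.seg_pos / seg_len : 0.0;
          double f1 = seg_len > 0 ? (a.seg_pos + adv) / seg_len : 1.0;
          double x0 = g.x[u] + f0 * (g.x[v] - g.x[u]);
          double y0 = g.y[u] + f0 * (g.y[v] - g.y[u]);
          double x1 = g.x[u] + f1 * (g.x[v] - g.x[u]);
          double y1 = g.y[u] + f1 * (g.y[v] - g.y[u]);
          // sensor entries on this sub-segment
          for (int sN = 0; sN < n_s; ++sN) {
            char& ins = inside[(size_t)i * n_s + sN];
            bool end_in = euclid(x1, y1, s_x[sN], s_y[sN]) <= s_r[sN];
            if (!ins) {
              if (seg_point_dist(x0, y0, x1, y1, s_x[sN], s_y[sN]) <= s_r[sN]) {
                if (record) {
                  footfall(sN, (sod * step_min) / 60)++;
                  ev_agent.push_back(i + 1);
                  ev_sensor.push_back(sN + 1);
                  ev_step.push_back(sod);
                }
              }
            }
            ins = end_in ? 1 : 0;
          }
          a.seg_pos += adv;
          remaining -= adv;
          a.px = x1; a.py = y1;
          if (a.seg_pos >= seg_len - 1e-9) {   // reached next node
            a.seg++;
            a.seg_pos = 0.0;
            if (a.seg >= (int)a.path.size() - 1) {   // arrived
              a.travelling = false;
              a.node = a.dest_node;
              a.px = g.x[a.node]; a.py = g.y[a.node];
              a.cur = a.dest_act;
              a.elapsed = 0;
              break;
            }
          }
        }
        // the arrival step still counts as travel; the destination
        // activity is first logged (and first decays) on the next step
        if (record) log_mat(i, sod) = 0;
        continue;
      }

      // 3. performing this step
      a.elapsed++;
      if (record) log_mat(i, sod) = a.cur + 1;
    }
  }

  return List::create(
    _["footfall"] = footfall,
    _["log"] = log_mat,
    _["event_agent"] = wrap(ev_agent),
    _["event_sensor"] = wrap(ev_sensor),
    _["event_step"] = wrap(ev_step));
}
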