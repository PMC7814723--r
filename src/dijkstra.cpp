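#include <Rcpp.h>
#include <queue>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Multi-source Dijkstra over the 8-connected grid graph.
// speed: km/h per cell, 0 (or NA) = impassable. cell_size in meters.
// sources: 1-based (row, col) matrix, each on a passable cell.
// Edge cost between adjacent cells a,b: half the step length traversed at
// each cell's speed, t = (d/2)/v_a + (d/2)/v_b, returned in minutes.
// [[Rcpp::export(name = ".grid_dijkstra")]]
NumericMatrix grid_dijkstra(NumericMatrix speed, double cell_size,
                            IntegerMatrix sources) {
  const int nr = speed.nrow(), nc = speed.ncol();
  const double d_km = cell_size / 1000.0;
  std::vector<double> dist((size_t)nr * nc,
                           std::numeric_limits<double>::infinity());
  typedef std::pair<double, int> Node;
  std::priority_queue<Node, std::vector<Node>, std::greater<Node> > pq;

  for (int s = 0; s < sources.nrow(); ++s) {
    int r = sources(s, 0) - 1, c = sources(s, 1) - 1;
    if (r < 0 || r >= nr || c < 0 || c >= nc)
      stop("source outside grid");
    double v = speed(r, c);
    if (!(v > 0.0)) stop("source on an impassable cell");
    int id = c * nr + r;
    if (dist[id] > 0.0) {
      dist[id] = 0.0;
      pq.push(Node(0.0, id));
    }
  }
  if (pq.empty()) stop("empty source set");

  const int dr[8] = {-1, -1, -1, 0, 0, 1, 1, 1};
  const int dc[8] = {-1, 0, 1, -1, 1, -1, 0, 1};
  const double sqrt2 = std::sqrt(2.0);

  while (!pq.empty()) {
    Node top = pq.top(); pq.pop();
    double d0 = top.first; int id = top.second;
    if (d0 > dist[id]) continue;
    int r = id % nr, c = id / nr;
    double va = speed(r, c);
    for (int k = 0; k < 8; ++k) {
      int r2 = r + dr[k], c2 = c + dc[k];
      if (r2 < 0 || r2 >= nr || c2 < 0 || c2 >= nc) continue;
      double vb = speed(r2, c2);
      if (!(vb > 0.0)) continue;
      double len = d_km * ((dr[k] != 0 && dc[k] != 0) ? sqrt2 : 1.0);
      double t = 60.0 * (len / 2.0) * (1.0 / va + 1.0 / vb);
      int id2 = c2 * nr + r2;
      if (d0 + t < dist[id2]) {
        dist[id2] = d0 + t;
        pq.push(Node(dist[id2], id2));
      }
    }
  }

  NumericMatrix out(nr, nc);
  for (int c = 0; c < nc; ++c)
    for (int r = 0; r < nr; ++r)
      out(r, c) = dist[(size_t)c * nr + r];
  return out;
}
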