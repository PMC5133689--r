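{
  "type": "FeatureCollection",
  "name": "tz_us_simplified",
  "description": "SIMPLIFIED synthetic meridian-slab approximation of the four continental-US time zones, for tests and synthetic scenarios only. Boundaries are straight meridians and do NOT follow real zone borders; supply real tz boundary polygons for production use.",
  "features": [
    {
      "type": "Feature",
      "properties": { "tz_id": "America/New_York" },
      "geometry": { "type": "Polygon", "coordinates": [[
        [-87.0, 24.5], [-66.9, 24.5], [-66.9, 49.5], [-87.0, 49.5], [-87.0, 24.5]
      ]] }
    },
    {
      "type": "Feature",
      "properties": { "tz_id": "America/Chicago" },
      "geometry": { "type": "Polygon", "coordinates": [[
        [-102.0, 24.5], [-87.0, 24.5], [-87.0, 49.5], [-102.0, 49.5], [-102.0, 24.5]
      ]] }
    },
    {
      "type": "Feature",
      "properties": { "tz_id": "America/Denver" },
      "geometry": { "type": "Polygon", "coordinates": [[
        [-114.0, 24.5], [-102.0, 24.5], [-102.0, 49.5], [-114.0, 49.5], [-114.0, 24.5]
      ]] }
    },
    {
      "type": "Feature",
      "properties": { "tz_id": "America/Los_Angeles" },
      "geometry": { "type": "Polygon", "coordinates": [[
        [-125.0, 24.5], [-114.0, 24.5], [-114.0, 49.5], [-125.0, 49.5], [-125.0, 24.5]
      ]] }
    }
  ]
}
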