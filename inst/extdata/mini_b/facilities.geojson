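{"type":"FeatureCollection","features":[{"type":"Feature","properties":{"id":1,"group":"health_services","subtype":"health_services","zone":"B"},"geometry":{"type":"Point","coordinates":[1065.81434067339,1000]}},{"type":"Feature","properties":{"id":2,"group":"municipal","subtype":"municipal","zone":"B"},"geometry":{"type":"Point","coordinates":[1111.68034614529,1000]}},{"type":"Feature","properties":{"id":3,"group":"shopping","subtype":"shopping","zone":"B"},"geometry":{"type":"Point","coordinates":[1000,1151.92652023397]}},{"type":"Feature","properties":{"id":4,"group":"shopping","subtype":"shopping","zone":"B"},"geometry":{"type":"Point","coordinates":[1000,1053.22608647402]}},{"type":"Feature","properties":{"id":5,"group":"shopping","subtype":"shopping","zone":"B"},"geometry":{"type":"Point","coordinates":[1400,1018.13762839884]}}]}
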