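{"mode":"uni","n":10,"baseSeed":9,"config":{"mode":"uni","pathLength":300,"nFrames":300,"nPerDirection":30,"speedRange":[1,3],"speedNoise":0.1,"psfRange":[3,6],"survivalRate":0.01,"gapRate":0.035,"gapMeanLen":2,"maxGapLen":6,"targetSNR":1.2,"movieWidth":20,"amplitude":0.3},"samples":[{"sample":1,"seed":10,"snr":1.19864597260131,"nTracks":56},{"sample":2,"seed":11,"snr":1.19137270514598,"nTracks":59},{"sample":3,"seed":12,"snr":1.19871934392525,"nTracks":60},{"sample":4,"seed":13,"snr":1.19649000661801,"nTracks":58},{"sample":5,"seed":14,"snr":1.20319215452697,"nTracks":58},{"sample":6,"seed":15,"snr":1.20654421423879,"nTracks":58},{"sample":7,"seed":16,"snr":1.19489121392532,"nTracks":59},{"sample":8,"seed":17,"snr":1.1942562578633,"nTracks":59},{"sample":9,"seed":18,"snr":1.2022876584718,"nTracks":59},{"sample":10,"seed":19,"snr":1.1956578898052,"nTracks":59}]}
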