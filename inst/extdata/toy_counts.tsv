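gene	AL	DR
g01	100	105
g02	250	240
g03	100	1000
g04	80	85
g05	500	510
g06	40	35
g07	1000	990
g08	150	160
g09	0	0
g10	60	55
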