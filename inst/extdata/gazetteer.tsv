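United States	United States	alias
USA	United States	alias
U.S.A.	United States	alias
United States of America	United States	alias
United Kingdom	United Kingdom	alias
UK	United Kingdom	alias
U.K.	United Kingdom	alias
England	United Kingdom	alias
Scotland	United Kingdom	alias
Wales	United Kingdom	alias
China	China	alias
P.R. China	China	alias
PR China	China	alias
People's Republic of China	China	alias
Japan	Japan	alias
Germany	Germany	alias
Deutschland	Germany	alias
Canada	Canada	alias
Turkey	Turkey	alias
France	France	alias
Italy	Italy	alias
Italia	Italy	alias
Spain	Spain	alias
The Netherlands	The Netherlands	alias
Netherlands	The Netherlands	alias
Australia	Australia	alias
South Korea	South Korea	alias
Republic of Korea	South Korea	alias
Korea	South Korea	alias
Ankara	Turkey	hint
Calgary	Canada	hint
Boston	United States	hint
Shanghai	China	hint
Heidelberg	Germany	hint
Osaka	Japan	hint
Lyon	France	hint
Cambridge	United Kingdom	hint
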