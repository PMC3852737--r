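day,plant,pollinator,count
168,P01,A04,1
168,P02,A06,1
170,P01,A04,2
171,P05,A05,1
172,P01,A02,1
172,P03,A06,2
172,P05,A02,3
172,P05,A05,1
172,P06,A06,1
173,P01,A02,1
173,P01,A04,1
173,P02,A06,1
173,P02,A08,1
173,P03,A04,1
173,P05,A05,1
173,P05,A08,1
173,P06,A06,1
173,P08,A04,2
174,P01,A02,1
174,P02,A05,1
174,P05,A02,1
174,P05,A05,1
174,P08,A04,1
175,P02,A08,1
175,P05,A02,2
175,P05,A05,1
175,P05,A08,2
176,P01,A02,1
176,P01,A03,2
176,P01,A04,1
176,P02,A08,1
176,P03,A06,1
176,P05,A08,1
176,P06,A06,1
177,P01,A03,1
177,P01,A04,1
177,P02,A08,2
177,P03,A04,1
177,P06,A03,1
177,P08,A03,1
178,P01,A03,1
178,P01,A04,1
178,P02,A05,3
178,P02,A06,1
178,P03,A03,3
178,P03,A06,1
178,P05,A02,1
179,P01,A02,1
179,P01,A03,1
179,P02,A05,1
179,P02,A06,1
179,P03,A04,1
179,P05,A05,1
179,P06,A03,1
179,P06,A06,2
180,P02,A06,1
180,P05,A05,1
180,P06,A06,2
181,P03,A03,2
181,P03,A04,1
182,P01,A04,1
182,P03,A03,1
182,P05,A05,1
182,P06,A03,1
182,P06,A06,3
183,P01,A02,1
183,P02,A06,1
183,P03,A03,1
183,P05,A02,1
183,P05,A05,1
184,P03,A03,1
184,P05,A02,2
184,P06,A03,1
185,P02,A06,3
185,P03,A03,1
185,P03,A04,1
185,P05,A05,1
185,P06,A06,1
186,P02,A06,1
186,P05,A05,1
187,P01,A02,1
187,P01,A04,1
187,P02,A06,2
187,P03,A04,2
187,P03,A06,1
187,P05,A05,1
187,P06,A03,1
188,P01,A02,1
188,P01,A03,1
188,P02,A05,1
188,P02,A06,1
188,P03,A03,2
188,P05,A02,1
189,P01,A04,2
189,P03,A04,2
189,P05,A02,1
189,P06,A09,2
190,P01,A04,1
190,P02,A05,1
190,P03,A03,1
190,P03,A06,1
190,P05,A02,2
190,P05,A09,1
191,P01,A02,1
191,P01,A03,1
191,P05,A02,1
191,P05,A09,1
192,P02,A06,1
193,P02,A06,1
193,P05,A05,1
193,P06,A06,1
194,P02,A05,1
194,P05,A02,3
194,P05,A09,1
194,P06,A09,1
195,P02,A05,1
195,P02,A06,1
195,P05,A02,1
195,P06,A06,1
195,P06,A16,1
196,P02,A05,1
196,P02,A06,1
196,P02,A14,1
196,P05,A05,1
197,P04,A11,1
197,P04,A16,1
197,P05,A02,1
197,P05,A05,3
197,P05,A07,1
197,P05,A11,1
197,P07,A03,1
198,P04,A11,1
198,P04,A13,1
198,P05,A02,1
198,P05,A07,2
198,P05,A10,1
199,P04,A07,1
199,P04,A10,3
199,P04,A12,1
199,P05,A02,1
199,P05,A07,1
199,P05,A10,2
199,P05,A13,1
199,P05,A14,3
200,P05,A02,2
200,P05,A13,1
200,P05,A14,1
200,P05,A15,1
200,P07,A06,1
201,P05,A14,1
201,P07,A06,1
202,P05,A07,1
202,P05,A11,1
202,P05,A12,1
202,P05,A13,1
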